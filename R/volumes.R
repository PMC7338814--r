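#' Neighbourhood offsets for a 3-D connectivity scheme
#'
#' Returns the integer voxel offsets defining face (6), face+edge (18) or
#' face+edge+corner (26) adjacency.
#'
#' @param connectivity One of 6, 18 or 26.
#' @return Integer matrix with one offset per row and columns (dx, dy, dz).
#' @export
neighbour_offsets <- function(connectivity = 6) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6"  = d == 1,
    "18" = d >= 1 & d <= 2,
    "26" = d >= 1)
  storage.mode(off) <- "integer"
  unname(off[keep, , drop = FALSE])
}

check_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3-D array", name))
  invisible(x)
}

#' Shift a 3-D array by an integer voxel offset
#'
#' Voxels shifted in from outside the grid are filled with `fill`
#' (0/FALSE by default).
#'
#' @param a 3-D array.
#' @param s Integer offset of length 3.
#' @param fill Fill value for voxels entering from outside the grid.
#' @return Array of the same shape.
#' @export
shift_volume <- function(a, s, fill = vector(typeof(a), 1L)) {
  check_volume(a, "a")
  dm <- dim(a)
  s <- as.integer(s)
  out <- array(fill, dm)
  src <- lapply(1:3, function(i) {
    lo <- max(1L, 1L - s[i]); hi <- min(dm[i], dm[i] - s[i])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(src) == 0L)) return(out)
  dst <- lapply(1:3, function(i) src[[i]] + s[i])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation of a 3-D mask
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @param iterations Number of dilation passes.
#' @return Logical array.
#' @export
dilate_mask <- function(mask, connectivity = 6, iterations = 1) {
  check_volume(mask, "mask")
  off <- neighbour_offsets(connectivity)
  out <- mask != 0
  for (i in seq_len(iterations)) {
    acc <- out
    for (k in seq_len(nrow(off)))
      acc <- acc | shift_volume(out, off[k, ], fill = FALSE)
    out <- acc
  }
  out
}

#' Binary erosion of a 3-D mask
#'
#' Voxels outside the grid count as background, so the mask shrinks at the
#' image border as well as at internal boundaries.
#'
#' @inheritParams dilate_mask
#' @return Logical array.
#' @export
erode_mask <- function(mask, connectivity = 6, iterations = 1) {
  check_volume(mask, "mask")
  off <- neighbour_offsets(connectivity)
  out <- mask != 0
  for (i in seq_len(iterations)) {
    acc <- out
    for (k in seq_len(nrow(off)))
      acc <- acc & shift_volume(out, off[k, ], fill = FALSE)
    out <- acc
  }
  out
}

#' Label connected components of a 3-D binary mask
#'
#' Components are found under the requested voxel connectivity; labels are
#' dense positive integers, 0 marks background.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels.
#' @export
label_components <- function(mask, connectivity = 6) {
  check_volume(mask, "mask")
  dm <- dim(mask)
  idx <- which(mask != 0)
  lab <- array(0L, dm)
  n <- length(idx)
  if (n == 0L) return(lab)
  rank <- integer(prod(dm))
  rank[idx] <- seq_len(n)
  coord <- arrayInd(idx, dm)
  off <- neighbour_offsets(connectivity)
  # half the offsets suffice for an undirected adjacency graph
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
           (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- coord
    nb[, 1] <- nb[, 1] + off[k, 1]
    nb[, 2] <- nb[, 2] + off[k, 2]
    nb[, 3] <- nb[, 3] + off[k, 3]
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    nb_rank <- rank[lin]
    src <- which(ok)
    has <- nb_rank > 0L
    if (any(has)) edges[[k]] <- cbind(src[has], nb_rank[has])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Edge effects are handled by renormalising with the in-grid kernel mass,
#' so a constant array stays constant.
#'
#' @param a Numeric 3-D array.
#' @param sigma_vox Kernel standard deviation per axis, in voxels.
#' @return Smoothed numeric array.
#' @export
gaussian_smooth_3d <- function(a, sigma_vox) {
  check_volume(a, "a")
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3L)
  a <- a * 1.0
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    acc <- array(0, dim(a))
    wsum <- array(0, dim(a))
    ones <- array(1, dim(a))
    for (j in seq_along(k)) {
      sh <- integer(3)
      sh[ax] <- j - r - 1L
      acc <- acc + k[j] * shift_volume(a, sh, fill = 0)
      wsum <- wsum + k[j] * shift_volume(ones, sh, fill = 0)
    }
    a <- acc / wsum
  }
  a
}

#' Integrate a (probabilistic) lesion map into millilitres
#'
#' @param values Numeric 3-D array of per-voxel values (binary or
#'   probabilities in `[0, 1]`).
#' @param voxel_mm Voxel dimensions in mm (length 3).
#' @return Volume in ml.
#' @export
integrate_volume <- function(values, voxel_mm) {
  check_volume(values, "values")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be three positive values")
  sum(values) * prod(voxel_mm) / 1000
}

#' Geodesic (layered) voxel distance from a source mask
#'
#' Breadth-first layer distance (in dilation steps under the given
#' connectivity) from `source`, constrained to propagate through `domain`.
#' Unreached voxels get `Inf`.
#'
#' @param source Logical array of source voxels.
#' @param domain Logical array through which distance propagates.
#' @param connectivity 6, 18 or 26.
#' @param max_steps Safety cap on propagation passes.
#' @return Numeric array: 0 on `source`, k on domain voxels reached at pass k.
#' @export
bfs_distance <- function(source, domain, connectivity = 6,
                         max_steps = sum(dim(source))) {
  check_volume(source, "source")
  dist <- array(Inf, dim(source))
  dist[source != 0] <- 0
  frontier <- source != 0
  reach <- domain != 0
  for (k in seq_len(max_steps)) {
    grown <- dilate_mask(frontier, connectivity) & reach & !is.finite(dist)
    if (!any(grown)) break
    dist[grown] <- k
    frontier <- grown
  }
  dist
}
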