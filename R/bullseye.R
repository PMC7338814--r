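## Bullseye coordinate system: the white-matter + deep-grey volume between
## the ventricular surface and the cortical sheet is divided into four
## equidistant layers by solving the Laplace equation with Dirichlet values
## 0 (ventricles) and 1 (cortex), then crossed with nine lobar labels to
## give 36 regions.

#' Solve the discrete Laplace equation on a voxel domain
#'
#' Dirichlet problem on a 7-point stencil (spacing-aware weights): phi = 0
#' on `inner`, phi = 1 on `outer`, discrete-harmonic in between. Domain
#' faces with no neighbour act as Neumann (no-flux) boundaries. Solved
#' directly as a sparse symmetric positive-definite system.
#'
#' @param domain Logical array: solve region including both boundaries.
#' @param inner Logical array of inner (phi = 0) boundary voxels.
#' @param outer Logical array of outer (phi = 1) boundary voxels.
#' @param voxel_mm Voxel dimensions in mm.
#' @param tol Maximum admissible residual of the discrete system.
#' @return Numeric array: phi in [0, 1] on the domain, NA outside.
#' @export
solve_laplace <- function(domain, inner, outer, voxel_mm = c(1, 1, 1),
                          tol = 1e-5) {
  check_volume(domain, "domain")
  dm <- dim(domain)
  dom <- domain != 0 | inner != 0 | outer != 0
  inn <- inner != 0
  out <- outer != 0
  if (!any(inn) || !any(out)) stop("inner and outer boundaries must be nonempty")
  if (any(inn & out)) stop("inner and outer boundaries must be disjoint")

  unknown <- dom & !inn & !out
  phi <- array(NA_real_, dm)
  phi[inn] <- 0
  phi[out] <- 1
  if (!any(unknown)) return(phi)

  ## every unknown voxel must reach a boundary through the domain
  reach <- bfs_distance(inn | out, dom, connectivity = 6)
  if (any(!is.finite(reach[unknown])))
    stop(sprintf("%d domain voxel(s) have no path to either boundary",
                 sum(!is.finite(reach[unknown]))))

  idxU <- which(unknown)
  nU <- length(idxU)
  rank <- integer(prod(dm)); rank[idxU] <- seq_len(nU)
  coord <- arrayInd(idxU, dm)
  w_axis <- 1 / as.numeric(voxel_mm)^2

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nU)
  b <- numeric(nU)
  fixed_val <- array(NA_real_, dm)
  fixed_val[inn] <- 0; fixed_val[out] <- 1

  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    w <- w_axis[which(o != 0)]
    nb <- coord
    nb[, 1] <- nb[, 1] + o[1]; nb[, 2] <- nb[, 2] + o[2]; nb[, 3] <- nb[, 3] + o[3]
    okg <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
           nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- rep(NA_integer_, nU)
    lin[okg] <- nb[okg, 1] + (nb[okg, 2] - 1L) * dm[1] +
                (nb[okg, 3] - 1L) * dm[1] * dm[2]
    in_dom <- okg & dom[ifelse(is.na(lin), 1L, lin)] & !is.na(lin)
    if (!any(in_dom)) next
    diag_acc[in_dom] <- diag_acc[in_dom] + w
    nb_rank <- rank[lin[in_dom]]
    src <- which(in_dom)
    free <- nb_rank > 0L
    if (any(free)) {
      ii <- c(ii, src[free]); jj <- c(jj, nb_rank[free])
      xx <- c(xx, rep(-w, sum(free)))
    }
    if (any(!free)) {
      fix <- src[!free]
      b[fix] <- b[fix] + w * fixed_val[lin[in_dom][!free]]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nU)), j = c(jj, seq_len(nU)),
                            x = c(xx, diag_acc), dims = c(nU, nU))
  ## A is symmetric positive definite: solve with sparse Cholesky
  A <- Matrix::forceSymmetric(A)
  sol <- as.numeric(Matrix::solve(A, b))
  res <- max(abs(as.numeric(A %*% sol) - b))
  if (res > tol)
    stop(sprintf("Laplace solve residual %.3g exceeds tol %.3g", res, tol))
  phi[idxU] <- pmin(pmax(sol, 0), 1)
  phi
}

#' Bin a Laplace field into equidistant layers
#'
#' Layer k covers phi in [(k-1)/n, k/n) with the final layer closed at
#' phi = 1, so the ventricular surface is layer 1 and the cortical sheet
#' layer n.
#'
#' @param phi Laplace field array (NA outside the domain).
#' @param n_layers Number of layers (default 4).
#' @return Integer array of layer labels (0 outside the domain).
#' @export
assign_layers <- function(phi, n_layers = 4L) {
  check_volume(phi, "phi")
  lay <- array(0L, dim(phi))
  ok <- is.finite(phi)
  lay[ok] <- pmin(as.integer(floor(phi[ok] * n_layers)) + 1L, n_layers)
  lay
}

#' Combine layer and lobe labels into the bullseye parcellation
#'
#' @param layers Integer layer array (1..n_layers on the domain, 0 outside).
#' @param lobe_labels Integer lobe array with exactly `n_lobes` categories
#'   covering the domain.
#' @param n_layers,n_lobes Parcellation dimensions (defaults 4 x 9 = 36).
#' @return Object of class `bullseye_parcellation`: arrays `layer`, `lobe`,
#'   `region` (region id = (lobe - 1) * n_layers + layer) and a lookup
#'   data frame `regions`.
#' @export
combine_parcellation <- function(layers, lobe_labels, n_layers = 4L,
                                 n_lobes = 9L) {
  check_volume(layers, "layers")
  dom <- layers > 0
  if (any(lobe_labels[dom] < 1L | lobe_labels[dom] > n_lobes))
    stop(sprintf("%d domain voxel(s) lack a lobe label in 1..%d",
                 sum(lobe_labels[dom] < 1L | lobe_labels[dom] > n_lobes),
                 n_lobes))
  region <- array(0L, dim(layers))
  region[dom] <- (lobe_labels[dom] - 1L) * n_layers + layers[dom]
  lut <- expand.grid(layer = seq_len(n_layers), lobe = seq_len(n_lobes))
  lut$region <- (lut$lobe - 1L) * n_layers + lut$layer
  structure(list(layer = layers, lobe = lobe_labels, region = region,
                 n_layers = n_layers, n_lobes = n_lobes, regions = lut),
            class = "bullseye_parcellation")
}

#' Propagate lobe labels onto unlabelled domain voxels
#'
#' Iterative nearest-label dilation: each pass assigns to every unlabelled
#' domain voxel the smallest label among its already-labelled 26-neighbours
#' (smallest-label tie-break makes the result independent of visit order).
#'
#' @param lobe_labels Integer array (0 = unlabelled).
#' @param domain Logical array of voxels that must end up labelled.
#' @return Integer lobe array covering the domain.
#' @export
propagate_lobes <- function(lobe_labels, domain) {
  lab <- lobe_labels
  off <- neighbour_offsets(26)
  repeat {
    todo <- domain != 0 & lab == 0L
    if (!any(todo)) break
    best <- array(Inf, dim(lab))
    for (k in seq_len(nrow(off))) {
      nb <- shift_volume(lab, off[k, ], fill = 0L)
      cand <- ifelse(nb > 0L, nb, Inf)
      best <- pmin(best, cand)
    }
    newly <- todo & is.finite(best)
    if (!any(newly)) stop("some domain voxels are unreachable from any label")
    lab[newly] <- as.integer(best[newly])
  }
  lab
}

#' Aggregate a value map over bullseye regions
#'
#' Per-region sums in ml, optionally normalised by total error volume or by
#' a true-positive volume. Regions with a zero denominator report 0 and are
#' flagged.
#'
#' @param value_map Nonnegative array (binary error mask or probabilities).
#' @param parcellation A `bullseye_parcellation`.
#' @param voxel_mm Voxel dimensions in mm.
#' @param normalizer "none", "total_error" (divide by the map's own total)
#'   or "tp_volume" (divide by `tp_ml`).
#' @param tp_ml True-positive volume in ml (required for "tp_volume").
#' @return Data frame: region, layer, lobe, ml, proportion,
#'   zero_denominator.
#' @export
aggregate_regions <- function(value_map, parcellation, voxel_mm = c(1, 1, 1),
                              normalizer = c("none", "total_error",
                                             "tp_volume"),
                              tp_ml = NULL) {
  normalizer <- match.arg(normalizer)
  if (any(value_map < 0)) stop("value_map must be nonnegative")
  lut <- parcellation$regions
  vox_ml <- prod(voxel_mm) / 1000
  dom <- parcellation$region > 0
  sums <- numeric(nrow(lut))
  if (any(dom & value_map != 0)) {
    agg <- tapply(value_map[dom], parcellation$region[dom], sum)
    sums[as.integer(names(agg))] <- as.numeric(agg) * vox_ml
  }
  denom <- switch(normalizer,
    none = 1,
    total_error = sum(sums),
    tp_volume = {
      if (is.null(tp_ml)) stop("tp_ml is required for normalizer='tp_volume'")
      tp_ml
    })
  zero_denom <- denom <= 0
  prop <- if (zero_denom) rep(0, length(sums)) else sums / denom
  data.frame(region = lut$region, layer = lut$layer, lobe = lut$lobe,
             ml = sums, proportion = prop,
             zero_denominator = zero_denom)
}

#' Polar wedge geometry for plotting a bullseye
#'
#' Plot-ready wedge coordinates: one angular sector per lobe, one radial
#' band per layer (radius grows with distance from the ventricles).
#'
#' @param parcellation A `bullseye_parcellation`.
#' @return Data frame with region, layer, lobe, theta_start, theta_end,
#'   r_inner, r_outer (angles in degrees).
#' @export
bullseye_wedges <- function(parcellation) {
  lut <- parcellation$regions
  n_lobes <- parcellation$n_lobes
  n_layers <- parcellation$n_layers
  data.frame(
    region = lut$region, layer = lut$layer, lobe = lut$lobe,
    theta_start = (lut$lobe - 1) * 360 / n_lobes,
    theta_end = lut$lobe * 360 / n_lobes,
    r_inner = (lut$layer - 1) / n_layers,
    r_outer = lut$layer / n_layers)
}
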