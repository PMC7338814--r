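## Semi-automated gold-standard protocol: median-brain-intensity thresholds
## (scanner-specific percentages), seed-grown components, manual edits, and
## the nested 3-of-4 majority-vote consensus.

#' Scanner threshold table
#'
#' Default high/low segmentation thresholds and maximum viewing intensity,
#' all as percentages of median whole-brain intensity. GE scans carry a
#' hyperintense posterior bias, so their thresholds are raised.
#'
#' @param scanner One of "Siemens", "Philips", "GE"; NULL returns the table.
#' @return A one-row data frame (or the full table) with columns scanner,
#'   high_pct, low_pct, view_max_pct.
#' @export
scanner_thresholds <- function(scanner = NULL) {
  tab <- data.frame(
    scanner = c("Siemens", "Philips", "GE"),
    high_pct = c(130, 130, 145),
    low_pct = c(120, 120, 130),
    view_max_pct = c(238, 238, 340),
    stringsAsFactors = FALSE)
  if (is.null(scanner)) return(tab)
  row <- tab[tab$scanner == scanner, ]
  if (nrow(row) != 1L)
    stop("unknown scanner '", scanner, "'; use Siemens, Philips or GE")
  row
}

#' Median whole-brain intensity
#'
#' @param flair FLAIR intensity array.
#' @param brain_mask Logical brain mask (nonempty).
#' @return The median intensity over mask voxels (mean of the central pair
#'   for even counts).
#' @export
median_brain_intensity <- function(flair, brain_mask) {
  idx <- which(brain_mask != 0)
  if (!length(idx)) stop("brain mask is empty")
  stats::median(flair[idx])
}

#' Threshold a FLAIR image at a percentage of median brain intensity
#'
#' A voxel is included iff its intensity is at least `median * pct / 100`
#' (inclusive comparison; set `strict_gt = TRUE` for a strict cut), within
#' the brain mask.
#'
#' @param flair FLAIR intensity array.
#' @param median_intensity Median whole-brain intensity (> 0).
#' @param pct Threshold as a percentage of the median.
#' @param brain_mask Optional logical mask restricting the map.
#' @param strict_gt Use strictly-greater comparison instead of >=.
#' @return Logical array.
#' @export
threshold_map <- function(flair, median_intensity, pct, brain_mask = NULL,
                          strict_gt = FALSE) {
  if (median_intensity <= 0) stop("median_intensity must be > 0")
  cut <- median_intensity * pct / 100
  out <- if (strict_gt) flair > cut else flair >= cut
  if (!is.null(brain_mask)) out <- out & (brain_mask != 0)
  out
}

#' Grow a lesion from a seed voxel on a threshold map
#'
#' Returns the connected component of the threshold map containing the seed
#' (empty if the seed voxel is below threshold).
#'
#' @param thr_map Logical threshold map.
#' @param seed Integer voxel index triple (1-based).
#' @param connectivity 6, 18 or 26 (default 6: face-adjacent growth).
#' @return Logical array holding the seed's component.
#' @export
grow_from_seed <- function(thr_map, seed, connectivity = 6) {
  check_volume(thr_map, "thr_map")
  dm <- dim(thr_map)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dm))
    stop("seed must be a voxel index inside the grid")
  out <- array(FALSE, dm)
  if (!thr_map[seed[1], seed[2], seed[3]]) return(out)
  lab <- label_components(thr_map, connectivity)
  out[lab == lab[seed[1], seed[2], seed[3]]] <- TRUE
  out
}

#' Apply manual edits to a segmentation
#'
#' Additions are unioned in, removals subtracted; a voxel present in both
#' sets is removed (removals take precedence).
#'
#' @param mask Logical segmentation array.
#' @param additions,removals Voxel index matrices (rows = voxels, 3 columns)
#'   or logical arrays.
#' @return Edited logical array.
#' @export
apply_edits <- function(mask, additions = NULL, removals = NULL) {
  check_volume(mask, "mask")
  as_mask <- function(x) {
    if (is.null(x)) return(array(FALSE, dim(mask)))
    if (is.array(x) && length(dim(x)) == 3L) return(x != 0)
    x <- matrix(as.integer(x), ncol = 3)
    if (any(x < 1L) || any(sweep(x, 2, dim(mask), ">") ))
      stop("edit voxels must lie inside the grid")
    out <- array(FALSE, dim(mask))
    out[x] <- TRUE
    out
  }
  (mask != 0 | as_mask(additions)) & !as_mask(removals)
}

#' Nested majority-vote consensus of four rater segmentations
#'
#' Each of the four leave-one-out triplets (123, 124, 234, 134) votes a
#' voxel positive iff at least 2 of its 3 raters marked it; the overall
#' consensus marks a voxel positive iff at least `overall_min` of the 4
#' triplet votes are positive. The strict default (3) resolves the 2-2 tie
#' downward; `overall_min = 2` is the permissive alternative.
#'
#' @param raters List of exactly 4 logical arrays on one grid.
#' @param overall_min Minimum positive triplet votes (default 3).
#' @return Logical consensus array.
#' @export
consensus_segmentation <- function(raters, overall_min = 3L) {
  if (length(raters) != 4L) stop("exactly 4 rater segmentations are required")
  dm <- dim(raters[[1]])
  if (!all(vapply(raters, function(r) identical(dim(r), dm), TRUE)))
    stop("rater masks must share one grid")
  r <- lapply(raters, function(x) x != 0)
  triplets <- list(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  votes <- array(0L, dm)
  for (tr in triplets) {
    s <- r[[tr[1]]] + r[[tr[2]]] + r[[tr[3]]]
    votes <- votes + (s >= 2L)
  }
  votes >= overall_min
}

#' Mean relative volume difference against a reference rater
#'
#' Helper for rater acceptance checks: mean of |v - ref| / ref over a
#' training set of paired volumes.
#'
#' @param volumes,reference Equal-length positive volume vectors.
#' @return Mean relative difference (0.15 was the historical acceptance bar).
#' @export
mean_volume_difference <- function(volumes, reference) {
  if (length(volumes) != length(reference))
    stop("volumes and reference must have equal length")
  if (any(reference <= 0)) stop("reference volumes must be positive")
  mean(abs(volumes - reference) / reference)
}
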