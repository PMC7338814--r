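## Agreement and error metrics between segmentations: Dice overlap,
## detection/outline error decomposition (per connected lesion), confusion
## summary, absolute-agreement ICC, Bland-Altman limits and paired
## log2-volume tests.

#' Dice overlap coefficient
#'
#' 2|S∩R| / (|S| + |R|). Two empty masks agree trivially and score 1.
#'
#' @param S,R Logical arrays on one grid.
#' @return Dice score in [0, 1].
#' @export
dice <- function(S, R) {
  if (!identical(dim(S), dim(R)))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(S), collapse = "x"), paste(dim(R), collapse = "x")))
  s <- S != 0; r <- R != 0
  denom <- sum(s) + sum(r)
  if (denom == 0) return(1)
  2 * sum(s & r) / denom
}

#' Detection/outline error decomposition of a segmentation pair
#'
#' Two segmentations share a lesion when the corresponding connected
#' components intersect in at least one voxel. Components of S with no
#' intersection with R contribute their voxels as detection-error false
#' positives (DEFP); components of R absent from S are detection-error false
#' negatives (DEFN). Within shared lesions, S-only voxels are outline-error
#' false positives (OEFP) and R-only voxels outline-error false negatives
#' (OEFN). TP = |S∩R|. Conservation: OEFP+DEFP = |S\\R| and OEFN+DEFN =
#' |R\\S|.
#'
#' @param S Segmentation under assessment (logical array).
#' @param R Reference segmentation (logical array, same grid).
#' @param connectivity Component connectivity (default 18, matching the
#'   segmenter's first-stage definition; 6 and 26 are also accepted).
#' @param voxel_mm Voxel dimensions for the ml columns.
#' @return Object of class `error_decomposition`: voxel counts and ml for
#'   TP, OEFP, OEFN, DEFP, DEFN plus per-component assignments.
#' @export
decompose_errors <- function(S, R, connectivity = 18, voxel_mm = c(1, 1, 1)) {
  if (!identical(dim(S), dim(R)))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(S), collapse = "x"), paste(dim(R), collapse = "x")))
  s <- S != 0; r <- R != 0
  labS <- label_components(s, connectivity)
  labR <- label_components(r, connectivity)
  nS <- max(labS); nR <- max(labR)

  S_shared <- if (nS > 0) {
    hits <- tapply(r[labS != 0], labS[labS != 0], any)
    as.logical(hits)
  } else logical(0)
  R_shared <- if (nR > 0) {
    hits <- tapply(s[labR != 0], labR[labR != 0], any)
    as.logical(hits)
  } else logical(0)

  s_only <- s & !r
  r_only <- r & !s
  defp_mask <- s_only & array(labS %in% which(!S_shared) & labS != 0, dim(s))
  oefp_mask <- s_only & !defp_mask
  defn_mask <- r_only & array(labR %in% which(!R_shared) & labR != 0, dim(r))
  oefn_mask <- r_only & !defn_mask

  counts <- c(TP = sum(s & r), OEFP = sum(oefp_mask), OEFN = sum(oefn_mask),
              DEFP = sum(defp_mask), DEFN = sum(defn_mask))
  vox_ml <- prod(voxel_mm) / 1000
  structure(list(
    counts = counts, ml = counts * vox_ml,
    voxel_mm = voxel_mm, connectivity = connectivity,
    seg_components = data.frame(component = seq_len(nS),
                                shared = S_shared),
    ref_components = data.frame(component = seq_len(nR),
                                shared = R_shared),
    masks = list(OEFP = oefp_mask, OEFN = oefn_mask,
                 DEFP = defp_mask, DEFN = defn_mask,
                 TP = s & r)), class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat("Detection/outline error decomposition (voxels | ml)\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-5s %8d | %8.4f\n", nm, x$counts[[nm]], x$ml[[nm]]))
  invisible(x)
}

#' Confusion summary over segmentation pairs
#'
#' Sums TP, FP (split into outline and detection error) and FN (same split)
#' in millilitres over a list of (segmentation, reference) pairs, each on
#' its own grid with its own voxel size.
#'
#' @param pairs List of lists with elements `S`, `R` and `voxel_mm`.
#' @param connectivity Component connectivity for the DE/OE split.
#' @return A list with `tp_ml`, `fp_ml`, `fp_oe_ml`, `fp_de_ml`, `fn_ml`,
#'   `fn_oe_ml`, `fn_de_ml` and a printable 2x2 `table`.
#' @export
confusion_summary <- function(pairs, connectivity = 18) {
  acc <- c(TP = 0, OEFP = 0, OEFN = 0, DEFP = 0, DEFN = 0)
  for (p in pairs) {
    d <- decompose_errors(p$S, p$R, connectivity = connectivity,
                          voxel_mm = p$voxel_mm %||% c(1, 1, 1))
    acc <- acc + d$ml
  }
  tab <- matrix(c(NA, acc[["OEFN"]] + acc[["DEFN"]],
                  acc[["OEFP"]] + acc[["DEFP"]], acc[["TP"]]),
                2, 2, byrow = TRUE,
                dimnames = list(reference = c("No lesion", "Lesion"),
                                segmentation = c("No lesion", "Lesion")))
  list(tp_ml = acc[["TP"]],
       fp_ml = acc[["OEFP"]] + acc[["DEFP"]],
       fp_oe_ml = acc[["OEFP"]], fp_de_ml = acc[["DEFP"]],
       fn_ml = acc[["OEFN"]] + acc[["DEFN"]],
       fn_oe_ml = acc[["OEFN"]], fn_de_ml = acc[["DEFN"]],
       table = tab)
}

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1) from the two-way random-effects mean squares (between-subject,
#' between-rater, error), with the standard F-based 95% confidence interval.
#' Agreement (not consistency): a constant offset between raters lowers the
#' coefficient.
#'
#' @param measurements Subjects-by-raters numeric matrix, no missing cells.
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci` (length 2), and the mean squares.
#' @export
icc_agreement <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(m)) stop("missing cells are not supported")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + MSC + MSE < 1e-300)
    stop("zero total variance: ICC undefined")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
       ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci = c(lower = lower, upper = upper),
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k)
}

#' Bland-Altman agreement of two volume series
#'
#' Differences d = a - b; limits of agreement are mean(d) +/- 1.96 SD(d)
#' (sample SD). Also returns the (mean, difference) pairs for plotting.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff` and a
#'   data frame `points` with columns mean and diff.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between a and b")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md,
       loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
       sd_diff = sdd,
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Paired t-test on log2-transformed volumes
#'
#' WMH volume distributions are right-skewed, so paired comparisons are run
#' on log2 volumes; the mean difference is then a log2 volume ratio.
#'
#' @param a,b Equal-length positive volume vectors (length >= 2).
#' @return List with `t`, `p`, `df`, `mean_log2_diff`.
#' @export
paired_log2_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between a and b")
  if (any(a <= 0) || any(b <= 0)) stop("volumes must be positive")
  d <- log2(a) - log2(b)
  if (stats::sd(d) == 0) {
    ## degenerate case t.test refuses: identical (or exactly shifted) pairs
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = length(d) - 1, mean_log2_diff = md))
  }
  ht <- stats::t.test(log2(a), log2(b), paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_log2_diff = unname(ht$estimate))
}
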