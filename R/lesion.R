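## From fitted mixture to final WMH mask: outlierness scoring against the
## healthy white-matter inliers, two-threshold candidate selection with
## small-cluster rescue, 18-then-6 connectivity classification, rule-based
## false-positive correction and probabilistic volume integration.

wm_inlier_components <- function(model) {
  cls <- comp_classes(model)
  parts <- comp_parts(model)
  which(cls == "WM" & parts == "inlier")
}

## weight-averaged WM inlier mean intensity for one modality
wm_inlier_mean <- function(model, modality_col) {
  ks <- wm_inlier_components(model)
  if (!length(ks)) stop("model has no WM inlier component")
  w <- vapply(model$components[ks], `[[`, 0, "weight")
  mu <- vapply(model$components[ks], function(cp) cp$mean[modality_col], 0)
  sum(w * mu) / sum(w)
}

#' Outlierness map from a converged fit
#'
#' Per-voxel score: squared Mahalanobis distance to the nearest WM inlier
#' component, kept only on voxels whose total outlier-part responsibility
#' exceeds their inlier responsibility AND whose FLAIR intensity exceeds the
#' WM inlier FLAIR mean (the hyperintensity constraint); everywhere else the
#' score is 0.
#'
#' @param fit A `model_fit`.
#' @param Y Voxel-by-modality intensity matrix (masked voxels).
#' @param flair_col Column of `Y` holding FLAIR intensities.
#' @return Numeric score vector (one per row of `Y`), all finite and >= 0.
#' @export
compute_outlierness <- function(fit, Y, flair_col = match("flair", colnames(Y))) {
  model <- fit$model
  ks <- wm_inlier_components(model)
  if (!length(ks)) stop("model has no WM inlier component")
  if (is.na(flair_col)) stop("cannot locate the FLAIR column of Y")
  score <- rep(Inf, nrow(Y))
  for (k in ks) {
    cp <- model$components[[k]]
    score <- pmin(score, sq_mahalanobis(Y, cp$mean, cp$cov))
  }
  parts <- comp_parts(model)
  r_out <- rowSums(fit$responsibilities[, parts == "outlier", drop = FALSE])
  candidate <- r_out > 0.5 & Y[, flair_col] > wm_inlier_mean(model, flair_col)
  score[!candidate] <- 0
  score
}

#' Two-stage 18-then-6 connected-component classification
#'
#' Stage 1 labels components under 18-connectivity; stage 2 re-partitions
#' each 18-component under 6-connectivity, so that downstream rules can act
#' on the finer 6-subcomponents while consulting the 18-parent (regions of
#' mixed origin are not discarded wholesale).
#'
#' @param mask Logical 3-D array.
#' @return List with integer label arrays `label18`, `label6` and an integer
#'   vector `parent18` mapping each 6-label to its 18-parent.
#' @export
classify_components <- function(mask) {
  check_volume(mask, "mask")
  label18 <- label_components(mask, connectivity = 18)
  label6 <- label_components(mask, connectivity = 6)
  n6 <- max(label6)
  parent18 <- integer(n6)
  if (n6 > 0) {
    idx <- which(mask != 0)
    parent18[label6[idx]] <- label18[idx]
  }
  list(label18 = label18, label6 = label6, parent18 = parent18)
}

candidate_table <- function(score_arr, labels, pass) {
  n <- max(labels$label6)
  if (n == 0L)
    return(data.frame(component = integer(0), parent18 = integer(0),
                      size = integer(0), mean_score = numeric(0),
                      pass = character(0)))
  idx <- which(labels$label6 != 0)
  lab <- labels$label6[idx]
  data.frame(
    component = seq_len(n),
    parent18 = labels$parent18,
    size = as.integer(tabulate(lab, n)),
    mean_score = as.numeric(tapply(score_arr[idx], lab, mean)),
    pass = pass)
}

#' Select primary lesion candidates above the outlierness threshold
#'
#' @param score_arr 3-D outlierness score array (0 outside candidates).
#' @param T Positive primary threshold; voxels with score >= T are selected.
#' @return Object of class `candidate_set`: list with the binary `mask`,
#'   component `labels` (18-then-6) and a per-component `table`.
#' @export
select_candidates <- function(score_arr, T) {
  check_volume(score_arr, "score_arr")
  if (T <= 0) stop("T must be > 0")
  mask <- score_arr >= T
  labels <- classify_components(mask)
  structure(list(mask = mask, labels = labels, threshold = T,
                 table = candidate_table(score_arr, labels, "primary")),
            class = "candidate_set")
}

#' Rescue small hyperintense clusters at a reduced threshold
#'
#' Components of the score >= 2T/3 field that are disjoint from every primary
#' candidate and smaller than 60 voxels are added with pass "rescued";
#' primary candidates are never altered.
#'
#' @param score_arr 3-D outlierness score array.
#' @param candidates A `candidate_set` built with the same `T`.
#' @param T The primary threshold used for `candidates`.
#' @param max_size Strict upper size bound for rescued clusters (default 60:
#'   clusters with fewer than 60 voxels qualify).
#' @return Updated `candidate_set` including rescued components.
#' @export
rescue_small_clusters <- function(score_arr, candidates, T, max_size = 60L) {
  stopifnot(inherits(candidates, "candidate_set"))
  low_mask <- score_arr >= (2 * T / 3)
  low_labels <- classify_components(low_mask)
  keep <- candidates$mask
  n6 <- max(low_labels$label6)
  rescued <- array(FALSE, dim(score_arr))
  if (n6 > 0) {
    idx <- which(low_labels$label6 != 0)
    lab <- low_labels$label6[idx]
    sizes <- tabulate(lab, n6)
    touches_primary <- tapply(candidates$mask[idx], lab, any)
    ok <- which(sizes < max_size & !touches_primary)
    if (length(ok))
      rescued[idx[lab %in% ok]] <- TRUE
  }
  mask <- keep | rescued
  labels <- classify_components(mask)
  idx <- which(mask)
  pass <- ifelse(rescued[idx], "rescued", "primary")
  tab <- candidate_table(score_arr, labels, "primary")
  if (nrow(tab)) {
    lab6 <- labels$label6[idx]
    comp_pass <- tapply(pass, lab6, function(p)
      if (all(p == "rescued")) "rescued" else "primary")
    tab$pass <- as.character(comp_pass[as.character(tab$component)])
  }
  structure(list(mask = mask, labels = labels, threshold = candidates$threshold,
                 rescued_mask = rescued, table = tab),
            class = "candidate_set")
}

#' Rule-based false-positive correction
#'
#' Removes candidate 6-subcomponents that (a) lie more than half outside the
#' brain mask, (b) sit in likely choroid plexus / ventricle (mean CSF prior
#' > 0.5), (c) are not hyperintense on FLAIR relative to every normal
#' parenchymal tissue (the maximum of the WM and GM inlier FLAIR means --
#' WMH outshine grey matter as well as white),
#' (d) fall outside the supratentorial mask, (e) are smaller than
#' `min_size_vox` voxels (isolated voxels at the tail of the noise
#' distribution are indistinguishable from artefact), or (f) sit in tissue
#' the atlas calls grey matter rather than white (mean WM prior below
#' `wm_prior_floor`; deep grey nuclei and choroid-plexus-like structures are
#' the classic wrongly-classified hyperintensities). Survivors carry their
#' outlier-part responsibility as a per-voxel probability.
#'
#' @param candidates A `candidate_set`.
#' @param fit The `model_fit` that produced the candidates.
#' @param flair FLAIR intensity array.
#' @param mask Logical analysis mask matching the fit (rows of `Y`).
#' @param brain_mask Logical brain mask.
#' @param csf_prior CSF atlas probability array.
#' @param supratentorial Logical supratentorial mask.
#' @param min_size_vox Minimum surviving component size in voxels.
#' @param wm_prior WM atlas probability array (NULL disables rule (f)).
#' @param wm_prior_floor Minimum mean WM prior for a surviving component.
#' @return Object of class `lesion_mask`: list with probabilistic `prob`,
#'   binary `mask` (prob >= 0.5) and a per-component `table` recording any
#'   removal rule.
#' @export
correct_false_positives <- function(candidates, fit, flair, mask,
                                    brain_mask, csf_prior, supratentorial,
                                    min_size_vox = 5L,
                                    wm_prior = NULL, wm_prior_floor = 0.2) {
  missing_ctx <- c()
  if (is.null(brain_mask)) missing_ctx <- c(missing_ctx, "brain_mask")
  if (is.null(csf_prior)) missing_ctx <- c(missing_ctx, "csf_prior")
  if (is.null(supratentorial)) missing_ctx <- c(missing_ctx, "supratentorial")
  if (length(missing_ctx))
    stop("missing context masks: ", paste(missing_ctx, collapse = ", "))

  model <- fit$model
  flair_col <- match("flair", c("t1", "flair"))
  wm_flair <- wm_inlier_mean(model, flair_col)
  ## brightest normal parenchyma: WMH must exceed GM as well as WM
  cls <- comp_classes(model)
  parts_all <- comp_parts(model)
  gm_in <- which(cls == "GM" & parts_all == "inlier")
  hyper_ref <- max(c(wm_flair, vapply(model$components[gm_in],
                                      function(cp) cp$mean[flair_col], 0)))

  lab6 <- candidates$labels$label6
  n6 <- max(lab6)
  prob <- array(0, dim(lab6))
  removed_by <- character(n6)
  if (n6 > 0) {
    ## per-voxel outlier-part responsibility mapped back into the volume
    parts <- comp_parts(model)
    r_out_vec <- rowSums(fit$responsibilities[, parts == "outlier",
                                              drop = FALSE])
    r_out <- array(0, dim(lab6))
    r_out[which(mask != 0)] <- r_out_vec

    idx <- which(lab6 != 0)
    lab <- lab6[idx]
    frac_in_brain <- tapply(brain_mask[idx], lab, mean)
    mean_csf <- tapply(csf_prior[idx], lab, mean)
    mean_flair <- tapply(flair[idx], lab, mean)
    frac_supra <- tapply(supratentorial[idx], lab, mean)

    sizes <- tabulate(lab, n6)
    removed_by[frac_in_brain <= 0.5] <- "outside_brain"
    removed_by[removed_by == "" & mean_csf > 0.5] <- "csf"
    removed_by[removed_by == "" & mean_flair <= hyper_ref] <- "not_hyperintense"
    removed_by[removed_by == "" & frac_supra <= 0.5] <- "infratentorial"
    removed_by[removed_by == "" & sizes < min_size_vox] <- "too_small"
    if (!is.null(wm_prior)) {
      mean_wm <- tapply(wm_prior[idx], lab, mean)
      removed_by[removed_by == "" & mean_wm < wm_prior_floor] <- "low_wm_prior"
    }

    keep <- which(removed_by == "")
    sel <- idx[lab %in% keep]
    prob[sel] <- r_out[sel]
  }
  tab <- candidates$table
  if (nrow(tab)) tab$removed_by <- removed_by[tab$component]
  structure(list(prob = prob, mask = prob >= 0.5, table = tab),
            class = "lesion_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full WMH segmentation of a co-registered T1/FLAIR pair
#'
#' Runs the whole automated chain: atlas-moment initialisation, EM, bias
#' field estimation and correction, EM refit, initial outlier map and
#' outlier re-seeding, optional split-and-merge model selection, outlierness
#' scoring, two-threshold candidate selection with small-cluster rescue, and
#' false-positive correction.
#'
#' @param t1,flair Co-registered intensity arrays.
#' @param atlas Named list of class prior arrays (GM, WM, CSF, nonbrain).
#' @param mask Logical analysis mask (brain plus adjacent non-brain shell).
#' @param brain_mask Logical brain mask (subset of `mask`).
#' @param voxel_mm Voxel dimensions in mm.
#' @param supratentorial Logical supratentorial mask; defaults to
#'   `brain_mask`.
#' @param outlier_threshold Primary outlierness threshold; defaults to the
#'   0.95 chi-square quantile with df = number of modalities.
#' @param bias_order Polynomial bias order (0 disables correction).
#' @param max_components_per_class Split-and-merge cap (1 disables search).
#' @param tol,max_iter EM convergence controls.
#' @return Object of class `wmh_segmentation`: the fit, outlierness array,
#'   candidate set, lesion probability/binary maps and integrated volume.
#' @export
segment_wmh <- function(t1, flair, atlas, mask, brain_mask, voxel_mm,
                        supratentorial = NULL,
                        outlier_threshold = NULL,
                        bias_order = 3L,
                        max_components_per_class = 3L,
                        tol = 1e-5, max_iter = 60L) {
  images <- list(t1 = t1, flair = flair)
  if (!all(vapply(images, function(im) identical(dim(im), dim(mask)), TRUE)))
    stop("t1, flair and mask must share one grid")
  supratentorial <- supratentorial %||% brain_mask
  Y <- masked_matrix(images, mask)
  A <- atlas_matrix(atlas, mask)
  M <- ncol(Y)
  T0 <- outlier_threshold %||% stats::qchisq(0.95, df = M)

  model <- init_model(Y, A)
  model <- robustify_model(model, Y, A)
  fit <- fit_em(model, Y, A, tol = tol, max_iter = max_iter)

  if (bias_order > 0) {
    bias <- estimate_bias_field(images, fit$responsibilities, fit$model,
                                mask, order = bias_order)
    images <- correct_bias(images, bias)
    Y <- masked_matrix(images, mask)
    fit <- fit_em(fit$model, Y, A, tol = tol, max_iter = max_iter)
  } else bias <- NULL

  score0 <- initial_outlier_map(fit, Y, A)
  model <- boost_outliers(fit, Y, A, score0)
  fit <- fit_em(model, Y, A, tol = tol, max_iter = max_iter)
  if (max_components_per_class > 1L)
    fit <- split_merge_search(fit, Y, A,
                              max_components_per_class = max_components_per_class)

  score <- compute_outlierness(fit, Y)
  score_arr <- array(0, dim(mask))
  score_arr[which(mask != 0)] <- score

  cand <- select_candidates(score_arr, T0)
  cand <- rescue_small_clusters(score_arr, cand, T0)
  lesion <- correct_false_positives(cand, fit, images$flair, mask,
                                    brain_mask, atlas$CSF, supratentorial,
                                    wm_prior = atlas$WM)
  structure(list(
    fit = fit, bias = bias, outlierness = score_arr, candidates = cand,
    lesion_prob = lesion$prob, lesion_mask = lesion$mask,
    component_table = lesion$table,
    volume_ml = integrate_volume(lesion$prob, voxel_mm),
    voxel_mm = voxel_mm, threshold = T0), class = "wmh_segmentation")
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat("WMH segmentation\n")
  cat(sprintf("  threshold T = %.3f, %d candidate component(s)\n",
              x$threshold, nrow(x$candidates$table)))
  cat(sprintf("  lesion volume: %.3f ml (probabilistic integration)\n",
              x$volume_ml))
  invisible(x)
}
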