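## Synthetic multimodal brain phantom: nested-ellipsoid anatomy with planted
## WMH of three morphologies, multiplicative polynomial bias and additive
## Gaussian noise. Tissue label codes are fixed package-wide.

#' Tissue label codes used by the phantom
#'
#' Integer codes: 0 background (air), 1 GM, 2 WM, 3 CSF (ventricles),
#' 4 non-brain (skull/scalp shell), 5 deep GM (basal ganglia + thalamus).
#'
#' @export
tissue_codes <- function() {
  c(background = 0L, GM = 1L, WM = 2L, CSF = 3L, nonbrain = 4L, deepGM = 5L)
}

#' Default noiseless tissue intensities
#'
#' Rows are tissue classes, columns modalities (t1, flair), in arbitrary
#' scanner units. CSF is dark on FLAIR (fluid suppression) and dark on T1;
#' WM is bright on T1 and mid-grey on FLAIR; the skull/scalp shell is
#' T1-bright (fat).
#'
#' @return Numeric matrix with rownames GM, WM, CSF, nonbrain, deepGM.
#' @export
default_tissue_means <- function() {
  m <- rbind(
    GM       = c(t1 = 110, flair = 120),
    WM       = c(t1 = 140, flair = 100),
    CSF      = c(t1 = 50,  flair = 40),
    nonbrain = c(t1 = 160, flair = 70),
    deepGM   = c(t1 = 120, flair = 112))
  m
}

#' Specify a synthetic brain phantom
#'
#' Bundles every generator parameter. Lesion contrast is expressed relative
#' to white matter: FLAIR multiplier > 1 (hyperintense) and T1 multiplier
#' < 1 (hypointense).
#'
#' @param grid_shape Integer triple of voxel grid dimensions.
#' @param voxel_mm Positive voxel dimensions in mm.
#' @param target_lesion_ml Total planted lesion volume in ml (>= 0).
#' @param lesion_mix Named proportions over punctate, confluent,
#'   periventricular morphologies; must sum to 1.
#' @param tissue_means Per-class per-modality noiseless intensities
#'   (see [default_tissue_means()]).
#' @param lesion_contrast Named numeric: `flair` multiplier (> 1) and `t1`
#'   multiplier (< 1) applied to the WM means.
#' @param bias_amplitude Peak relative amplitude of the multiplicative
#'   polynomial bias field (0 disables it).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer RNG seed; the whole phantom is deterministic given it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 72L, 64L),
                         voxel_mm = c(1, 1, 1),
                         target_lesion_ml = 4,
                         lesion_mix = c(punctate = 0.25, confluent = 0.45,
                                        periventricular = 0.30),
                         tissue_means = default_tissue_means(),
                         lesion_contrast = c(flair = 1.5, t1 = 0.7),
                         bias_amplitude = 0.1,
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three integers, each >= 16, to host ",
         "ventricles and a cortical ribbon")
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be three positive values")
  if (target_lesion_ml < 0) stop("target_lesion_ml must be >= 0")
  want <- c("punctate", "confluent", "periventricular")
  if (!all(want %in% names(lesion_mix)))
    lesion_mix <- stats::setNames(rep_len(as.numeric(lesion_mix), 3L), want)
  lesion_mix <- lesion_mix[want]
  if (any(lesion_mix < 0) || abs(sum(lesion_mix) - 1) > 1e-8)
    stop("lesion_mix proportions must be nonnegative and sum to 1")
  if (!all(c("GM", "WM", "CSF", "nonbrain", "deepGM") %in% rownames(tissue_means)))
    stop("tissue_means must have rows GM, WM, CSF, nonbrain, deepGM")
  if (lesion_contrast[["flair"]] <= 1)
    stop("lesion_contrast['flair'] must exceed 1 (hyperintense on FLAIR)")
  if (lesion_contrast[["t1"]] >= 1)
    stop("lesion_contrast['t1'] must be below 1 (hypointense on T1)")
  if (bias_amplitude < 0 || noise_sd < 0)
    stop("bias_amplitude and noise_sd must be >= 0")
  structure(list(
    grid_shape = grid_shape, voxel_mm = voxel_mm,
    target_lesion_ml = as.numeric(target_lesion_ml),
    lesion_mix = lesion_mix, tissue_means = tissue_means,
    lesion_contrast = lesion_contrast,
    bias_amplitude = as.numeric(bias_amplitude),
    noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "phantom_spec")
}

## mm coordinates of every voxel, centred on the grid
grid_coords_mm <- function(grid_shape, voxel_mm) {
  ax <- lapply(1:3, function(i)
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * voxel_mm[i])
  list(
    x = array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape),
    y = array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
              grid_shape),
    z = array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape))
}

inside_ellipsoid <- function(co, semi, centre = c(0, 0, 0)) {
  ((co$x - centre[1]) / semi[1])^2 +
  ((co$y - centre[2]) / semi[2])^2 +
  ((co$z - centre[3]) / semi[3])^2 <= 1
}

## Nested-ellipsoid anatomy; returns the label volume plus the analytic
## surfaces needed downstream (ventricle border, cortical sheet, lobes).
phantom_anatomy <- function(spec) {
  tc <- tissue_codes()
  co <- grid_coords_mm(spec$grid_shape, spec$voxel_mm)
  half <- spec$grid_shape * spec$voxel_mm / 2
  head_semi <- 0.92 * half
  brain_semi <- 0.80 * head_semi
  wm_semi <- 0.80 * brain_semi

  head <- inside_ellipsoid(co, head_semi)
  brain <- inside_ellipsoid(co, brain_semi)
  wm <- inside_ellipsoid(co, wm_semi)

  vent_semi <- wm_semi * c(0.18, 0.50, 0.20)
  vent_off <- wm_semi[1] * 0.28
  vent <- inside_ellipsoid(co, vent_semi, c(-vent_off, 0, 0)) |
          inside_ellipsoid(co, vent_semi, c(+vent_off, 0, 0))

  dgm_semi <- wm_semi * c(0.16, 0.26, 0.22)
  dgm_off <- wm_semi[1] * 0.58
  dgm <- inside_ellipsoid(co, dgm_semi, c(-dgm_off, 0, 0)) |
         inside_ellipsoid(co, dgm_semi, c(+dgm_off, 0, 0))
  dgm <- dgm & wm & !vent

  labels <- array(tc[["background"]], spec$grid_shape)
  labels[head] <- tc[["nonbrain"]]
  labels[brain] <- tc[["GM"]]
  labels[wm] <- tc[["WM"]]
  labels[dgm] <- tc[["deepGM"]]
  labels[vent & brain] <- tc[["CSF"]]

  if (!any(labels == tc[["CSF"]]) || !any(labels == tc[["WM"]]))
    stop("grid too small to host ventricles inside the white matter; ",
         "increase grid_shape or decrease voxel_mm")

  domain <- labels == tc[["WM"]] | labels == tc[["deepGM"]]
  vent_mask <- labels == tc[["CSF"]]
  gm_mask <- labels == tc[["GM"]]
  touch <- dilate_mask(domain, 6)
  ventricle_surface <- vent_mask & touch
  cortical_sheet <- gm_mask & touch

  ## 9 lobar labels: 4 angular sectors per hemisphere in the sagittal
  ## (y = anterior, z = superior) plane, plus one subcortical label.
  theta <- atan2(co$y, co$z) * 180 / pi      # 0 = superior, 90 = anterior
  lobe_of <- function(th) {
    out <- integer(length(th))
    out[th > 45 & th <= 135] <- 1L                 # frontal
    out[th > -45 & th <= 45] <- 2L                 # parietal
    out[th > -135 & th <= -45] <- 3L               # temporal
    out[th > 135 | th <= -135] <- 4L               # occipital
    out
  }
  sector <- array(lobe_of(as.vector(theta)), spec$grid_shape)
  hemi <- array(ifelse(as.vector(co$x) < 0, 0L, 1L), spec$grid_shape)
  lobes <- array(0L, spec$grid_shape)
  brainish <- array(labels %in% c(tc[["GM"]], tc[["WM"]], tc[["CSF"]],
                                  tc[["deepGM"]]), spec$grid_shape)
  lobes[brainish] <- (sector[brainish] - 1L) * 2L + hemi[brainish] + 1L
  subcort <- dilate_mask(dgm, 6, iterations = 2L) & brainish
  lobes[subcort] <- 9L

  list(labels = labels, head_mask = head,
       brain_mask = brainish,
       ventricle_surface = ventricle_surface,
       cortical_sheet = cortical_sheet,
       lobe_labels = lobes)
}

## pick exactly n voxels: all complete BFS layers, then a random draw from
## the first incomplete layer so the realised count is exact
pick_by_layer <- function(dist, candidates, n) {
  sel <- array(FALSE, dim(dist))
  if (n <= 0) return(sel)
  d <- dist
  d[!candidates] <- Inf
  layers <- sort(unique(d[is.finite(d)]))
  got <- 0L
  for (lv in layers) {
    idx <- which(d == lv)
    if (got + length(idx) <= n) {
      sel[idx] <- TRUE
      got <- got + length(idx)
    } else {
      take <- sample(idx, n - got)
      sel[take] <- TRUE
      got <- n
    }
    if (got >= n) break
  }
  sel
}

#' Plant WMH lesions of three morphologies into a tissue label volume
#'
#' Periventricular lesions are shells grown from the ventricular border
#' through white matter; confluent lesions are superlevel sets of a smoothed
#' Gaussian random field; punctate lesions are spheres of radius 1-3 voxels
#' placed in deep white matter. All lesions stay inside the WM (plus deep-GM
#' margin) and never touch CSF or non-brain tissue. Uses the current RNG
#' state; seed beforehand for reproducibility.
#'
#' @param tissue_labels Integer label volume using [tissue_codes()].
#' @param spec A [phantom_spec()].
#' @return Logical lesion volume.
#' @export
plant_lesions <- function(tissue_labels, spec) {
  tc <- tissue_codes()
  check_volume(tissue_labels, "tissue_labels")
  wm <- tissue_labels == tc[["WM"]]
  vent <- tissue_labels == tc[["CSF"]]
  if (!any(wm) || !any(vent & dilate_mask(wm, 6)))
    stop("tissue_labels must contain WM and ventricle-adjacent voxels")
  voxel_ml <- prod(spec$voxel_mm) / 1000
  total_vox <- round(spec$target_lesion_ml / voxel_ml)
  lesions <- array(FALSE, dim(tissue_labels))
  if (total_vox <= 0) return(lesions)
  if (total_vox > 0.85 * sum(wm))
    stop(sprintf(
      "requested lesion load (%d voxels) exceeds 85%% of available WM (%d voxels)",
      total_vox, sum(wm)))
  quota <- round(spec$lesion_mix * total_vox)
  ## rounding drift goes to the largest share
  quota[which.max(quota)] <- quota[which.max(quota)] + (total_vox - sum(quota))

  vdist <- bfs_distance(vent, wm, connectivity = 6)

  ## periventricular caps: layered shells on the ventricular border
  if (quota[["periventricular"]] > 0) {
    pv <- pick_by_layer(vdist, wm, quota[["periventricular"]])
    lesions <- lesions | pv
  }

  ## confluent: top-k voxels of a smoothed random field in non-occupied WM
  if (quota[["confluent"]] > 0) {
    field <- gaussian_smooth_3d(
      array(stats::rnorm(prod(dim(wm))), dim(wm)),
      sigma_vox = 3 / spec$voxel_mm * min(spec$voxel_mm))
    allowed <- wm & !dilate_mask(lesions, 6)
    n <- min(quota[["confluent"]], sum(allowed))
    if (n > 0) {
      idx <- which(allowed)
      take <- idx[order(field[idx], decreasing = TRUE)[seq_len(n)]]
      lesions[take] <- TRUE
    }
  }

  ## punctate: spheres radius 1-3 voxels in deep WM, away from ventricles,
  ## deep GM and the GM ribbon; per-sphere exclusion zones keep components
  ## disjoint so each stays within the radius-3 ball bound
  if (quota[["punctate"]] > 0) {
    co <- grid_coords_mm(dim(wm), spec$voxel_mm)
    deep <- wm & vdist >= 4 & erode_mask(wm, 6)
    deep <- deep & !dilate_mask(tissue_labels == tc[["deepGM"]], 6)
    ball_vol <- c(7, 33, 123)      # discrete ball sizes at radii 1-3
    remaining <- quota[["punctate"]]
    repeat {
      if (remaining < 4L) break
      placed <- FALSE
      for (r in c(3L, 2L, 1L)) {
        if (r > 1L && ball_vol[r] > remaining * 1.3) next
        free <- deep & !dilate_mask(lesions, 26, iterations = r + 1L)
        idx <- which(free)
        if (!length(idx)) next
        ctr <- arrayInd(sample(idx, 1L), dim(wm))
        cx <- co$x[ctr[1], 1, 1]; cy <- co$y[1, ctr[2], 1]
        cz <- co$z[1, 1, ctr[3]]
        r_mm <- r * min(spec$voxel_mm)
        ball <- ((co$x - cx)^2 + (co$y - cy)^2 + (co$z - cz)^2) <= r_mm^2
        ball <- ball & wm & !lesions
        if (!any(ball)) next
        lesions <- lesions | ball
        remaining <- remaining - sum(ball)
        placed <- TRUE
        break
      }
      if (!placed) break
    }
  }

  ## top-up: if space limits left the realised load short (e.g. crowded
  ## punctate placement), grow the remainder from existing lesion borders
  ## through WM -- unless the mix is pure punctate, whose sphere bound we
  ## must not break
  shortfall <- total_vox - sum(lesions)
  if (shortfall > 0 && any(lesions) &&
      (spec$lesion_mix[["confluent"]] > 0 ||
       spec$lesion_mix[["periventricular"]] > 0)) {
    ldist <- bfs_distance(lesions, wm, connectivity = 6)
    ldist[lesions] <- Inf
    topup <- pick_by_layer(ldist, wm & !lesions, shortfall)
    lesions <- lesions | topup
  }
  lesions
}

## random low-order polynomial field, scaled so it spans exactly
## [1 - amplitude, 1 + amplitude] over the mask, then renormalised to mean 1
random_bias_field <- function(grid_shape, voxel_mm, mask, amplitude, order = 2L) {
  if (amplitude <= 0) return(array(1, grid_shape))
  co <- grid_coords_mm(grid_shape, voxel_mm)
  half <- grid_shape * voxel_mm / 2
  X <- polynomial_basis(cbind(as.vector(co$x) / half[1],
                              as.vector(co$y) / half[2],
                              as.vector(co$z) / half[3]), order)
  beta <- stats::rnorm(ncol(X))
  p <- array(as.vector(X %*% beta), grid_shape)
  pm <- p[mask]
  rng <- range(pm)
  if (diff(rng) < 1e-12) return(array(1, grid_shape))
  p <- 2 * (p - rng[1]) / diff(rng) - 1       # spans [-1, 1] over the mask
  field <- 1 + amplitude * p
  field / mean(field[mask])
}

#' Apply multiplicative bias and additive noise to phantom images
#'
#' The bias is a smooth low-order (<= 3) polynomial multiplicative field with
#' mean 1 over the brain mask (one independent field per modality); the noise
#' is additive zero-mean Gaussian. Uses the current RNG state.
#'
#' @param images Named list of 3-D intensity arrays (e.g. t1, flair).
#' @param mask Logical array over which the bias field is normalised.
#' @param voxel_mm Voxel dimensions in mm.
#' @param bias_amplitude Peak relative bias amplitude (>= 0).
#' @param noise_sd Additive noise SD (>= 0).
#' @param bias_order Polynomial order of the bias field (<= 3).
#' @return List with elements `images` (degraded), `bias` (list of fields).
#' @export
apply_bias_and_noise <- function(images, mask, voxel_mm,
                                 bias_amplitude, noise_sd, bias_order = 2L) {
  if (bias_amplitude < 0 || noise_sd < 0)
    stop("bias_amplitude and noise_sd must be >= 0")
  if (bias_order > 3L) stop("bias_order must be <= 3")
  out <- images
  bias <- vector("list", length(images))
  names(bias) <- names(images)
  for (nm in names(images)) {
    b <- random_bias_field(dim(images[[nm]]), voxel_mm, mask,
                           bias_amplitude, bias_order)
    v <- images[[nm]] * b
    if (noise_sd > 0)
      v <- v + array(stats::rnorm(length(v), sd = noise_sd), dim(v))
    out[[nm]] <- v
    bias[[nm]] <- b
  }
  list(images = out, bias = bias)
}

#' Smoothed tissue-probability atlas from a label volume
#'
#' One-hot class indicators smoothed with an isotropic Gaussian (in mm) and
#' renormalised so per-voxel probabilities sum to 1. Deep GM is folded into
#' the GM class, giving the four model classes GM, WM, CSF, non-brain.
#' Background air is assigned to the non-brain class.
#'
#' @param tissue_labels Integer label volume using [tissue_codes()].
#' @param voxel_mm Voxel dimensions in mm.
#' @param smoothing_mm Gaussian smoothing FWHM-like sigma in mm (0 = one-hot).
#' @return Named list of probability arrays (GM, WM, CSF, nonbrain).
#' @export
make_pseudo_atlas <- function(tissue_labels, voxel_mm, smoothing_mm = 2) {
  tc <- tissue_codes()
  check_volume(tissue_labels, "tissue_labels")
  groups <- list(
    GM = c(tc[["GM"]], tc[["deepGM"]]),
    WM = tc[["WM"]],
    CSF = tc[["CSF"]],
    nonbrain = c(tc[["nonbrain"]], tc[["background"]]))
  probs <- lapply(groups, function(codes) {
    ind <- array(as.numeric(tissue_labels %in% codes), dim(tissue_labels))
    if (smoothing_mm > 0)
      ind <- gaussian_smooth_3d(ind, sigma_vox = smoothing_mm / voxel_mm)
    ind
  })
  tot <- Reduce(`+`, probs)
  lapply(probs, function(p) p / tot)
}

#' Generate a seeded synthetic multimodal brain phantom
#'
#' Builds nested-ellipsoid anatomy (non-brain shell, cortical GM ribbon, WM
#' interior, two ellipsoidal ventricles, deep-GM nuclei), plants WMH of the
#' requested morphologies and load, maps labels to noiseless T1/FLAIR
#' intensities, and degrades them with a multiplicative bias field and
#' additive Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom`: list with t1, flair, their noiseless
#'   counterparts, truth_lesions, brain_mask, head_mask, tissue_labels,
#'   ventricle_surface, cortical_sheet, lobe_labels, bias fields and
#'   voxel_mm.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  anat <- phantom_anatomy(spec)
  lesions <- plant_lesions(anat$labels, spec)

  tm <- spec$tissue_means
  tc <- tissue_codes()
  code_rows <- c("GM", "WM", "CSF", "nonbrain", "deepGM")
  t1 <- array(0, spec$grid_shape)
  flair <- array(0, spec$grid_shape)
  for (rn in code_rows) {
    sel <- anat$labels == tc[[rn]]
    t1[sel] <- tm[rn, "t1"]
    flair[sel] <- tm[rn, "flair"]
  }
  t1[lesions] <- tm["WM", "t1"] * spec$lesion_contrast[["t1"]]
  flair[lesions] <- tm["WM", "flair"] * spec$lesion_contrast[["flair"]]

  degraded <- apply_bias_and_noise(
    list(t1 = t1, flair = flair), mask = anat$brain_mask,
    voxel_mm = spec$voxel_mm, bias_amplitude = spec$bias_amplitude,
    noise_sd = spec$noise_sd)

  structure(list(
    t1 = degraded$images$t1, flair = degraded$images$flair,
    t1_noiseless = t1, flair_noiseless = flair,
    bias = degraded$bias,
    truth_lesions = lesions,
    brain_mask = anat$brain_mask, head_mask = anat$head_mask,
    tissue_labels = anat$labels,
    ventricle_surface = anat$ventricle_surface,
    cortical_sheet = anat$cortical_sheet,
    lobe_labels = anat$lobe_labels,
    voxel_mm = spec$voxel_mm, spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic brain phantom\n")
  cat(sprintf("  grid: %s voxels of %s mm\n",
              paste(dim(x$t1), collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x")))
  cat(sprintf("  brain: %.1f ml, lesions: %.2f ml (target %.2f ml)\n",
              integrate_volume(x$brain_mask * 1, x$voxel_mm),
              integrate_volume(x$truth_lesions * 1, x$voxel_mm),
              x$spec$target_lesion_ml))
  invisible(x)
}
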