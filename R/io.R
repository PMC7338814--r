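## NIfTI I/O, configuration handling and the end-to-end pipeline.

#' Read a NIfTI volume
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param expect_dim Optional grid dimensions to enforce.
#' @return List with `data` (3-D array), `voxel_mm`, `affine`.
#' @export
read_volume <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  voxel_mm <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  if (!is.null(expect_dim) && !identical(dim(data), as.integer(expect_dim)))
    stop(sprintf("grid mismatch: file is %s, expected %s",
                 paste(dim(data), collapse = "x"),
                 paste(expect_dim, collapse = "x")))
  list(data = data, voxel_mm = as.numeric(voxel_mm),
       affine = RNifti::xform(img))
}

#' Write a 3-D array as NIfTI
#'
#' @param data Numeric/logical 3-D array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_mm Voxel dimensions in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, voxel_mm = c(1, 1, 1)) {
  check_volume(data, "data")
  img <- RNifti::asNifti(array(as.numeric(data), dim(data)))
  RNifti::pixdim(img) <- as.numeric(voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its package default.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    ## phantom
    grid_shape = c(64L, 72L, 64L),
    voxel_mm = c(1, 1, 1),
    target_lesion_ml = 4,
    lesion_mix = c(punctate = 0.25, confluent = 0.45, periventricular = 0.30),
    lesion_contrast = c(flair = 1.5, t1 = 0.7),
    bias_amplitude = 0.1,
    noise_sd = 5,
    atlas_smoothing_mm = 2,
    ## mixture / extraction
    outlier_kappa = 10,
    outlier_fraction = 0.01,
    outlier_quantile = 0.95,
    bias_order = 3L,
    max_components_per_class = 3L,
    em_tol = 1e-5,
    em_max_iter = 60L,
    rescue_max_size = 60L,
    ## semiauto
    scanner = "Siemens",
    high_pct = NULL, low_pct = NULL,   # NULL: take from scanner table
    consensus_overall_min = 3L,
    strict_gt = FALSE,
    grow_connectivity = 6L,
    ## evaluation / bullseye
    error_connectivity = 18L,
    n_layers = 4L,
    laplace_tol = 1e-5,
    run_bullseye = TRUE,
    ## misc
    seed = 1L,
    out_dir = NULL)
}

validate_config <- function(cfg) {
  if (!is.null(cfg$high_pct) && !is.null(cfg$low_pct) &&
      (cfg$high_pct <= cfg$low_pct || cfg$low_pct <= 100))
    stop("config requires high_pct > low_pct > 100")
  if (cfg$target_lesion_ml < 0) stop("config: target_lesion_ml must be >= 0")
  if (!cfg$error_connectivity %in% c(6, 18, 26))
    stop("config: error_connectivity must be 6, 18 or 26")
  if (!cfg$scanner %in% scanner_thresholds()$scanner)
    stop("config: unknown scanner '", cfg$scanner, "'")
  if (cfg$n_layers < 1) stop("config: n_layers must be >= 1")
  cfg
}

#' Load a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected, missing keys take the
#' package defaults, and basic range invariants are checked.
#'
#' @param path Path to a YAML config (NULL or empty file = all defaults).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      bad <- setdiff(names(user), names(cfg))
      if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
      for (nm in names(user)) {
        v <- user[[nm]]
        if (!is.null(names(cfg[[nm]])) && is.list(v)) v <- unlist(v)
        cfg[[nm]] <- v
      }
    }
  }
  if (is.null(cfg$high_pct))
    cfg$high_pct <- scanner_thresholds(cfg$scanner)$high_pct
  if (is.null(cfg$low_pct))
    cfg$low_pct <- scanner_thresholds(cfg$scanner)$low_pct
  validate_config(cfg)
}

## 32-bit FNV-1a hash of a string, as hex; used for the run manifest
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    ## xor the low byte (h may exceed .Machine$integer.max)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    ## 32-bit modular multiply by the FNV prime 16777619 = 403 + 256*65536
    h <- (h * 403 + ((h * 256) %% 2^32) * 65536) %% 2^32
  }
  ## h may exceed .Machine$integer.max: print as two hex half-words
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full phantom-to-metrics pipeline
#'
#' Generates (or loads) a multimodal volume pair, segments WMH with the
#' mixture-outlier model, evaluates the result against the planted truth
#' (Dice, volumes, detection/outline decomposition) and, optionally, maps
#' the errors into the bullseye parcellation. Writes NIfTI/CSV/JSON outputs
#' and a manifest when `config$out_dir` is set.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @return List with `phantom`, `segmentation`, `metrics`, `bullseye`
#'   (NULL unless requested) and `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(utils::modifyList(default_config(), config))
  spec <- phantom_spec(
    grid_shape = cfg$grid_shape, voxel_mm = cfg$voxel_mm,
    target_lesion_ml = cfg$target_lesion_ml, lesion_mix = cfg$lesion_mix,
    lesion_contrast = cfg$lesion_contrast,
    bias_amplitude = cfg$bias_amplitude, noise_sd = cfg$noise_sd,
    seed = cfg$seed)
  ph <- generate_phantom(spec)
  atlas <- make_pseudo_atlas(ph$tissue_labels, ph$voxel_mm,
                             smoothing_mm = cfg$atlas_smoothing_mm)
  seg <- segment_wmh(
    ph$t1, ph$flair, atlas, mask = ph$head_mask, brain_mask = ph$brain_mask,
    voxel_mm = ph$voxel_mm,
    outlier_threshold = stats::qchisq(cfg$outlier_quantile, df = 2),
    bias_order = cfg$bias_order,
    max_components_per_class = cfg$max_components_per_class,
    tol = cfg$em_tol, max_iter = cfg$em_max_iter)

  truth <- ph$truth_lesions
  dec <- decompose_errors(seg$lesion_mask, truth,
                          connectivity = cfg$error_connectivity,
                          voxel_mm = ph$voxel_mm)
  metrics <- list(
    dice = dice(seg$lesion_mask, truth),
    volume_ml = seg$volume_ml,
    truth_volume_ml = integrate_volume(truth * 1, ph$voxel_mm),
    decomposition = dec)

  bull <- NULL
  if (isTRUE(cfg$run_bullseye)) {
    tc <- tissue_codes()
    dom <- ph$tissue_labels == tc[["WM"]] | ph$tissue_labels == tc[["deepGM"]]
    phi <- solve_laplace(dom | ph$ventricle_surface | ph$cortical_sheet,
                         ph$ventricle_surface, ph$cortical_sheet,
                         voxel_mm = ph$voxel_mm, tol = cfg$laplace_tol)
    layers <- assign_layers(phi, cfg$n_layers)
    layers[!dom] <- 0L
    lobes <- propagate_lobes(ph$lobe_labels, dom)
    parc <- combine_parcellation(layers, lobes, n_layers = cfg$n_layers)
    err_total <- Reduce(`+`, lapply(dec$masks[c("OEFP", "OEFN", "DEFP",
                                                "DEFN")], function(m) m * 1))
    bull <- list(
      parcellation = parc,
      tables = lapply(dec$masks[c("OEFP", "OEFN", "DEFP", "DEFN")],
        function(m) aggregate_regions(m * 1, parc, ph$voxel_mm,
                                      normalizer = "total_error")),
      total_error_table = aggregate_regions(err_total, parc, ph$voxel_mm,
                                            normalizer = "total_error"),
      wedges = bullseye_wedges(parc))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wmhseg")),
    seed = cfg$seed,
    config_hash = fnv1a32(jsonlite::toJSON(
      cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)),
    dice = metrics$dice, volume_ml = metrics$volume_ml)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(seg$lesion_prob, file.path(cfg$out_dir, "lesion_prob.nii.gz"),
                 ph$voxel_mm)
    write_volume(seg$lesion_mask, file.path(cfg$out_dir, "lesion_mask.nii.gz"),
                 ph$voxel_mm)
    write_volume(ph$truth_lesions, file.path(cfg$out_dir, "truth.nii.gz"),
                 ph$voxel_mm)
    utils::write.csv(seg$component_table,
                     file.path(cfg$out_dir, "components.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(manifest, list(counts = as.list(dec$counts))),
      file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  list(phantom = ph, segmentation = seg, metrics = metrics,
       bullseye = bull, manifest = manifest)
}
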