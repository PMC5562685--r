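#' Build a pipeline run configuration
#'
#' Defaults reproduce the analysis settings of the adult-lifespan study
#' design this pipeline implements: 20 ICA components, 8 mm FWHM smoothing,
#' z-map threshold 3, trajectory orders 1-3, alpha 0.05 with Bonferroni
#' `m = K`, and age-range sensitivity bounds 80/70/60 years. Synthetic-mode
#' defaults additionally carry the generator settings (K_truth, cohort
#' size). The configuration round-trips losslessly through YAML.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param K number of ICA components.
#' @param fwhm_mm smoothing kernel FWHM (mm); `0` disables smoothing
#'   (pre-smoothed real inputs).
#' @param z_threshold z-map cluster threshold.
#' @param orders polynomial trajectory orders.
#' @param alpha family-wise significance level.
#' @param m Bonferroni test count (default `K`).
#' @param age_subsets upper age bounds for sensitivity analysis.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param min_voxels minimum cluster extent.
#' @param seed master seed; per-stage seeds are derived via [derive_seed()].
#' @param output_dir run directory for reports and the manifest.
#' @param n_subjects synthetic cohort size (`NULL` = the default 536-subject
#'   age-bin table).
#' @param K_truth number of latent synthetic sources.
#' @param write_nifti write per-component z-map NIfTI files.
#' @param volume_dir,mask_path,covariates_path real-mode input paths.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), K = 20L, fwhm_mm = 8,
                       z_threshold = 3, orders = 1:3, alpha = 0.05, m = K,
                       age_subsets = c(80, 70, 60), connectivity = 26L,
                       min_voxels = 0L, seed = 1L,
                       output_dir = tempfile("sbm_run_"),
                       n_subjects = NULL, K_truth = 4L, write_nifti = FALSE,
                       volume_dir = NULL, mask_path = NULL,
                       covariates_path = NULL) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, K = as.integer(K), fwhm_mm = fwhm_mm,
    z_threshold = z_threshold, orders = as.integer(orders), alpha = alpha,
    m = as.integer(m), age_subsets = age_subsets,
    connectivity = as.integer(connectivity),
    min_voxels = as.integer(min_voxels), seed = as.integer(seed),
    output_dir = output_dir, n_subjects = n_subjects,
    K_truth = as.integer(K_truth), write_nifti = write_nifti,
    volume_dir = volume_dir, mask_path = mask_path,
    covariates_path = covariates_path
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
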