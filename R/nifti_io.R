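#' Write a 3-D volume to a NIfTI-1 file
#'
#' The grid's affine is stored as the sform/qform so world coordinates
#' round-trip.
#'
#' @param volume 3-D array on `grid`.
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, grid, path) {
  stopifnot(identical(dim(volume), dim(grid$mask)))
  img <- RNifti::asNifti(volume)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume and its grid from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @param mask optional logical array to use as the grid mask.
#' @return List: `volume` (3-D array), `grid` ([volume_grid()] with the
#'   file's affine and voxel sizes).
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  affine <- RNifti::xform(img)
  vsize <- sqrt(colSums(affine[1:3, 1:3]^2))  # robust to missing pixdim
  grid <- volume_grid(dim(vol), vsize, affine = affine, mask = mask)
  list(volume = vol, grid = grid)
}

#' Export a synthetic cohort as per-subject NIfTI volumes
#'
#' Writes one volume per subject (out-of-mask voxels zero), the binary mask,
#' the covariate TSV, and a YAML ground-truth sidecar recording the seed and
#' generator settings.
#'
#' @param X an [data_matrix()] from [synthesize()].
#' @param gt the [ground_truth()] that generated it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort_nifti <- function(X, gt, dir) {
  stopifnot(inherits(X, "sbm_data_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- X$grid
  for (i in seq_len(nrow(X$values))) {
    write_volume(embed_volume(grid, X$values[i, ]), grid,
                 file.path(dir, paste0(X$cohort$id[i], ".nii.gz")))
  }
  write_volume(array(as.numeric(grid$mask), dim = grid$shape), grid,
               file.path(dir, "mask.nii.gz"))
  write_cohort(X$cohort, file.path(dir, "covariates.tsv"))
  spec <- list(
    seed = gt$seed, K = gt$K,
    residual_noise_sd = gt$residual_noise_sd, baseline = gt$baseline,
    loading_specs = lapply(gt$loading_specs, unclass)
  )
  yaml::write_yaml(spec, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Load a real-mode cohort: NIfTI volumes, mask and covariates
#'
#' Subject volumes are matched to covariate rows by `id` (file names
#' `<id>.nii` or `<id>.nii.gz`); unmatched ids are an error.
#'
#' @param volume_dir directory of per-subject NIfTI files.
#' @param mask_path NIfTI brain mask (non-zero = in-mask).
#' @param covariates_path covariate TSV (`id`, `age`, `sex`, `site`).
#' @return An [data_matrix()].
#' @export
load_cohort_nifti <- function(volume_dir, mask_path, covariates_path) {
  cohort <- read_cohort(covariates_path)
  mk <- read_volume(mask_path)
  mask <- mk$volume != 0
  grid <- volume_grid(mk$grid$shape, mk$grid$voxel_size,
                      affine = mk$grid$affine, mask = mask)
  paths <- file.path(volume_dir, paste0(cohort$id, ".nii.gz"))
  alt <- file.path(volume_dir, paste0(cohort$id, ".nii"))
  paths[!file.exists(paths)] <- alt[!file.exists(paths)]
  missing <- cohort$id[!file.exists(paths)]
  if (length(missing)) {
    stop("no volume found for subject id(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- t(vapply(paths, function(p) {
    mask_values(grid, read_volume(p)$volume)
  }, numeric(grid$n_voxels)))
  dimnames(vals) <- NULL
  data_matrix(vals, grid, cohort)
}
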