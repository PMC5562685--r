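#' Analysis-space geometry for volumetric maps
#'
#' A `volume_grid` bundles the array shape, voxel size, voxel-to-world affine
#' and brain mask that every volumetric operation in the package shares. World
#' coordinates are millimetres in an MNI-style frame (origin near the volume
#' centre unless a custom affine is given).
#'
#' @param shape integer length-3, voxels per axis (each >= 4).
#' @param voxel_size numeric length-3 (or scalar), mm per voxel along each axis.
#' @param affine 4x4 voxel-index-to-world-mm matrix applied to 0-based voxel
#'   indices. Default: diagonal scaling by `voxel_size` with the world origin
#'   at the volume centre.
#' @param mask logical 3-D array of `shape`, `TRUE` for in-analysis voxels.
#'   Default: all `TRUE`.
#' @return An object of class `volume_grid` with fields `shape`, `voxel_size`,
#'   `affine`, `mask`, plus cached `mask_idx` (linear indices of in-mask
#'   voxels) and `n_voxels`.
#' @examples
#' g <- volume_grid(c(8, 8, 8), 3)
#' g$n_voxels
#' @export
volume_grid <- function(shape, voxel_size, affine = NULL, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (any(shape < 4L)) stop("all grid shape entries must be >= 4")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  stopifnot(is.logical(mask), identical(dim(mask), dim(array(0, shape))))
  if (!any(mask)) stop("mask must contain at least one TRUE voxel")
  g <- list(
    shape = shape, voxel_size = voxel_size, affine = affine, mask = mask,
    mask_idx = which(mask), n_voxels = sum(mask)
  )
  class(g) <- "volume_grid"
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "volume_grid: %s voxels @ %s mm, %d in-mask (%.1f%%)\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$voxel_size, trim = TRUE), collapse = "x"),
    x$n_voxels, 100 * x$n_voxels / prod(x$shape)
  ))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param grid a [volume_grid()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param grid a [volume_grid()].
#' @param ijk numeric matrix (rows = voxels, 3 columns of 0-based indices) or
#'   a length-3 vector.
#' @return Matrix of world coordinates in mm (one row per voxel).
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  h <- cbind(ijk, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

# Convert linear array indices to 0-based (i,j,k) rows.
linear_to_ijk <- function(grid, idx) {
  a <- arrayInd(idx, grid$shape)
  a - 1L
}

#' Embed an in-mask vector into a full 3-D volume
#'
#' Out-of-mask voxels are filled with `fill` (default 0).
#' @param grid a [volume_grid()].
#' @param values numeric vector of length `grid$n_voxels`.
#' @param fill value for out-of-mask voxels.
#' @return A 3-D array of `grid$shape`.
#' @export
embed_volume <- function(grid, values, fill = 0) {
  stopifnot(length(values) == grid$n_voxels)
  vol <- array(fill, dim = grid$shape)
  vol[grid$mask_idx] <- values
  vol
}

#' Extract the in-mask voxel vector from a 3-D volume
#' @param grid a [volume_grid()].
#' @param volume 3-D array on `grid`.
#' @return Numeric vector of length `grid$n_voxels`.
#' @export
mask_values <- function(grid, volume) {
  stopifnot(identical(dim(volume), dim(grid$mask)))
  volume[grid$mask_idx]
}

#' Default desk-scale analysis grid
#'
#' A 24 x 28 x 24 grid at 3 mm isotropic resolution with an ellipsoidal brain
#' mask spanning 95% of each half-axis (about 6.4 thousand in-mask voxels):
#' large enough that spatial networks have room for bilateral structure, small
#' enough that a full decomposition runs in seconds.
#'
#' @return A [volume_grid()].
#' @export
default_grid <- function() {
  shape <- c(24L, 28L, 24L)
  centre <- (shape - 1) / 2
  semi <- 0.95 * (shape - 1) / 2
  idx <- arrayInd(seq_len(prod(shape)), shape)
  d2 <- ((idx[, 1] - 1 - centre[1]) / semi[1])^2 +
    ((idx[, 2] - 1 - centre[2]) / semi[2])^2 +
    ((idx[, 3] - 1 - centre[3]) / semi[3])^2
  mask <- array(d2 <= 1, dim = shape)
  volume_grid(shape, 3, mask = mask)
}
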