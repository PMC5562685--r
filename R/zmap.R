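#' Convert source rows into z-score volumes
#'
#' Each source row is standardized over in-mask voxels — `(value - mean)/SD`
#' — and embedded back into the 3-D grid with zeros outside the mask. The
#' transform is invariant to positive affine rescaling of a source, so
#' z-maps are comparable across components regardless of ICA scale.
#'
#' @param decomp an `sbm_decomposition` (or K x V source matrix).
#' @param grid the [volume_grid()] the source columns refer to.
#' @param threshold the z threshold later used for cluster extraction;
#'   stored with the maps (default 3, the conventional network-extent cut).
#' @return Object of class `sbm_zmap_set`: list `maps` of 3-D arrays,
#'   `grid`, `threshold`.
#' @export
zscore_sources <- function(decomp, grid, threshold = 3) {
  S <- if (inherits(decomp, "sbm_decomposition")) decomp$sources else
    as.matrix(decomp)
  stopifnot(ncol(S) == grid$n_voxels)
  maps <- lapply(seq_len(nrow(S)), function(k) {
    v <- S[k, ]
    s <- stats::sd(v)
    if (s < 1e-12) stop("source ", k, " has zero variance; cannot z-score")
    embed_volume(grid, (v - mean(v)) / s)
  })
  structure(list(maps = maps, grid = grid, threshold = threshold),
            class = "sbm_zmap_set")
}
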