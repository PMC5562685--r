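# Neighbourhood offsets for 6/18/26 connectivity in voxel index space.
connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  ord <- abs(off$di) + abs(off$dj) + abs(off$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  as.matrix(off[keep, ])
}

# Label the TRUE voxels of a logical 3-D array by connected component.
# Union-find over vectorized neighbour pairs; labels are arbitrary positive
# integers, 0 elsewhere.
label_components <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  idx <- which(bin)
  if (length(idx) == 0L) return(array(0L, dim = d))
  pos <- match(seq_len(prod(d)), idx)  # voxel -> node id or NA
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  co <- arrayInd(idx, d)
  offs <- connectivity_offsets(connectivity)
  # each unordered pair once: keep lexicographically positive offsets
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[r, 1]
    nj <- co[, 2] + offs[r, 2]
    nk <- co[, 3] + offs[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    if (!any(ok)) next
    nidx <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    nnode <- pos[nidx]
    a <- which(ok)[!is.na(nnode)]
    b <- nnode[!is.na(nnode)]
    for (q in seq_along(a)) {
      ra <- find(a[q])
      rb <- find(b[q])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- array(0L, dim = d)
  out[idx] <- labels
  out
}

#' Extract suprathreshold clusters from a z-map
#'
#' Connected components of `{z >= threshold}` under 6-, 18- or
#' 26-connectivity. Each cluster is reported with its voxel count, size in
#' mm^3 (voxel count times voxel volume), peak z value, and the peak's world
#' coordinate (affine applied to the in-cluster argmax; ties broken toward
#' the smallest linear index for determinism). Clusters are sorted by size
#' descending; clusters smaller than `min_voxels` are dropped. An empty
#' suprathreshold set yields a zero-row table, not an error.
#'
#' @param zmap 3-D numeric array on `grid`.
#' @param grid a [volume_grid()].
#' @param threshold positive z threshold.
#' @param connectivity 6, 18 or 26 (default 26, the common neuroimaging
#'   choice).
#' @param min_voxels minimum cluster extent in voxels (default 0).
#' @param negative_tail if `TRUE`, additionally label `{z <= -threshold}`
#'   clusters, flagged by `tail = "negative"` (peaks are then minima).
#' @return A data.frame with columns `cluster`, `tail`, `n_voxels`,
#'   `size_mm3`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_z`.
#' @export
extract_clusters <- function(zmap, grid, threshold = 3, connectivity = 26L,
                             min_voxels = 0L, negative_tail = FALSE) {
  stopifnot(threshold > 0, identical(dim(zmap), dim(grid$mask)))
  one_tail <- function(vol, tail) {
    lab <- label_components(vol >= threshold, connectivity)
    ids <- setdiff(unique(as.integer(lab)), 0L)
    rows <- lapply(ids, function(l) {
      vox <- which(lab == l)
      peak <- vox[which.max(vol[vox])]  # which.max: first max = smallest index
      ijk <- linear_to_ijk(grid, peak)
      w <- voxel_to_world(grid, ijk)
      z <- vol[peak]
      data.frame(
        tail = tail, n_voxels = length(vox),
        size_mm3 = length(vox) * voxel_volume(grid),
        peak_x_mm = w[1], peak_y_mm = w[2], peak_z_mm = w[3],
        peak_z = if (tail == "negative") -z else z
      )
    })
    do.call(rbind, rows)
  }
  out <- one_tail(zmap, "positive")
  if (negative_tail) out <- rbind(out, one_tail(-zmap, "negative"))
  if (is.null(out)) {
    out <- data.frame(tail = character(0), n_voxels = integer(0),
                      size_mm3 = numeric(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_z = numeric(0))
  }
  out <- out[out$n_voxels >= min_voxels, , drop = FALSE]
  out <- out[order(-out$size_mm3), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Tabulate clusters for every component of a z-map set
#'
#' @param zmaps an [zscore_sources()] result.
#' @param ... passed to [extract_clusters()]; the threshold defaults to the
#'   one stored in `zmaps`.
#' @param threshold overrides the stored threshold.
#' @return A data.frame with a leading `component` column.
#' @export
cluster_table <- function(zmaps, threshold = zmaps$threshold, ...) {
  stopifnot(inherits(zmaps, "sbm_zmap_set"))
  out <- lapply(seq_along(zmaps$maps), function(k) {
    tab <- extract_clusters(zmaps$maps[[k]], zmaps$grid,
                            threshold = threshold, ...)
    if (nrow(tab)) cbind(component = k, tab) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(component = integer(0), cluster = integer(0),
                      tail = character(0), n_voxels = integer(0),
                      size_mm3 = numeric(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_z = numeric(0))
  }
  rownames(out) <- NULL
  out
}
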