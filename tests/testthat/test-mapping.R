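test_that("z-scoring standardizes over the mask and is affine-invariant", {
  g <- tiny_grid()
  S <- tiny_sources(g, 2, seed = 81)
  zm <- zscore_sources(S, g)
  for (k in 1:2) {
    v <- mask_values(g, zm$maps[[k]])
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(stats::sd(v), 1, tolerance = 1e-10)
  }
  # already-standardized input is unchanged; positive affine maps collapse
  v1 <- mask_values(g, zscore_sources(S, g)$maps[[1]])
  v2 <- mask_values(g, zscore_sources(3.2 * S + 7, g)$maps[[1]])
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_error(zscore_sources(matrix(1, 1, g$n_voxels), g), "zero variance")
})

test_that("two disjoint blobs yield the hand-computed mm^3 sizes", {
  g <- volume_grid(c(12, 12, 12), 1.5)
  z <- array(0, g$shape)
  z[2:6, 2, 2] <- 4            # 5 voxels
  z[9:11, 9, 9] <- 5
  z[9:10, 10, 9] <- 5
  z[9:10, 9, 10] <- 5          # 7 voxels
  tab <- extract_clusters(z, g, threshold = 3)
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$size_mm3), c(5 * 3.375, 7 * 3.375))
})

test_that("single suprathreshold voxel reports its affine world peak", {
  g <- volume_grid(c(10, 10, 10), 2)
  z <- array(0, g$shape)
  z[4, 7, 2] <- 3.7
  tab <- extract_clusters(z, g, threshold = 3)
  expect_equal(nrow(tab), 1L)
  w <- voxel_to_world(g, c(3, 6, 1))  # 0-based indices
  expect_equal(c(tab$peak_x_mm, tab$peak_y_mm, tab$peak_z_mm),
               as.numeric(w))
  expect_equal(tab$peak_z, 3.7)
  expect_equal(tab$n_voxels, 1L)
})

test_that("labeling agrees with an independent flood-fill oracle", {
  set.seed(91)
  for (conn in c(6L, 18L, 26L)) {
    bin <- array(runif(20^3) < 0.25, c(20, 20, 20))
    mine <- sbmica:::label_components(bin, conn)
    oracle <- flood_fill_labels(bin, conn)
    expect_identical(partition_signature(mine), partition_signature(oracle))
  }
})

test_that("raising the threshold nests clusters and shrinks mass", {
  g <- tiny_grid()
  set.seed(92)
  z <- embed_volume(g, rnorm(g$n_voxels, 0, 2))
  lo <- extract_clusters(z, g, threshold = 2)
  hi <- extract_clusters(z, g, threshold = 3)
  expect_lte(sum(hi$n_voxels), sum(lo$n_voxels))
  # mass conservation at min_voxels = 0
  expect_equal(sum(lo$n_voxels), sum(z >= 2))
  expect_equal(sum(hi$n_voxels), sum(z >= 3))
  # every high-threshold cluster sits inside one low-threshold cluster
  lab_lo <- sbmica:::label_components(z >= 2, 26L)
  lab_hi <- sbmica:::label_components(z >= 3, 26L)
  for (l in setdiff(unique(as.integer(lab_hi)), 0L)) {
    parents <- unique(lab_lo[lab_hi == l])
    expect_length(parents, 1L)
    expect_true(all(parents > 0))
  }
})

test_that("connectivity partitions are nested 6 within 18 within 26", {
  set.seed(93)
  bin <- array(runif(15^3) < 0.2, c(15, 15, 15))
  l6 <- sbmica:::label_components(bin, 6L)
  l18 <- sbmica:::label_components(bin, 18L)
  l26 <- sbmica:::label_components(bin, 26L)
  refines <- function(fine, coarse) {
    for (l in setdiff(unique(as.integer(fine)), 0L)) {
      if (length(unique(coarse[fine == l])) != 1L) return(FALSE)
    }
    TRUE
  }
  expect_true(refines(l6, l18))
  expect_true(refines(l18, l26))
  expect_gte(max(l6), max(l18))
  expect_gte(max(l18), max(l26))
})

test_that("empty suprathreshold set and min_voxels filtering behave", {
  g <- tiny_grid()
  z <- embed_volume(g, rep(0, g$n_voxels))
  tab <- extract_clusters(z, g, threshold = 3)
  expect_equal(nrow(tab), 0L)
  z2 <- array(0, g$shape)
  z2[3, 3, 3] <- 4
  z2[7:8, 7, 7] <- 4
  filt <- extract_clusters(z2, g, threshold = 3, min_voxels = 2)
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$n_voxels, 2L)
})

test_that("negative tail is labelled separately when requested", {
  g <- tiny_grid()
  z <- array(0, g$shape)
  z[3, 3, 3] <- 4
  z[7, 7, 7] <- -4
  tab <- extract_clusters(z, g, threshold = 3, negative_tail = TRUE)
  expect_equal(sort(tab$tail), c("negative", "positive"))
  expect_equal(tab$peak_z[tab$tail == "negative"], -4)
})
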