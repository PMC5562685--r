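test_that("whitening yields identity covariance and stores its inverse path", {
  set.seed(10)
  X <- matrix(rnorm(30 * 400), 30, 400)
  red <- center_and_whiten(X, 5)
  expect_equal(dim(red$Y), c(5L, 400L))
  expect_equal(rowMeans(red$Y), rep(0, 5), tolerance = 1e-12)
  expect_equal(stats::cov(t(red$Y)), diag(5), tolerance = 1e-8)
  expect_error(center_and_whiten(X, 30), "exceeds")
})

test_that("noise-free K-source data retains > 0.999 variance in K axes", {
  g <- tiny_grid()
  gt <- ground_truth(g, K = 3, loading_specs = default_loading_specs()[1:3],
                     site_effect_sd = 0, sex_effect_sd = 0,
                     residual_noise_sd = 0, seed = 15)
  X <- synthesize(gt, quick_cohort(50, seed = 6))
  red <- center_and_whiten(X, 3)
  expect_gt(red$retained_variance, 0.999)
})

test_that("K = 1 whitening of rank-1 data recovers the standardized loading", {
  g <- tiny_grid()
  set.seed(11)
  w <- rnorm(25)
  s <- rnorm(g$n_voxels)
  X <- outer(w, s)
  red <- center_and_whiten(X, 1)
  # whitened row spans the single source direction up to sign
  expect_gt(abs(stats::cor(as.numeric(red$Y),
                           s - mean(s))), 1 - 1e-6)
})

test_that("infomax separates super-Gaussian toys and is seed-deterministic", {
  S <- laplace_sources(2, 5000, seed = 21)
  A <- matrix(c(2, 1, 1, 3), 2, 2)
  red <- center_and_whiten(rbind(A %*% S, rnorm(5000) * 0.01), 2)
  f1 <- infomax(red$Y, seed = 5)
  f2 <- infomax(red$Y, seed = 5)
  expect_identical(f1$W, f2$W)
  expect_true(f1$converged)
  # unmixed outputs match the true sources (scaled permutation)
  P <- stats::cor(t(f1$W %*% red$Y), t(S))
  expect_lt(amari_index(P), 0.05)
})

test_that("infomax agrees with the exhaustive-rotation kurtosis oracle", {
  for (s in 1:4) {
    S <- laplace_sources(2, 5000, seed = 100 + s)
    red <- center_and_whiten(rbind(S, rnorm(5000) * 0.01), 2)
    f <- infomax(red$Y, seed = s)
    oracle <- rotation_kurtosis_oracle(red$Y)
    expect_lt(amari_index(f$W %*% t(oracle$W)), 0.05)
  }
})

test_that("estimated source rows decorrelate after convergence", {
  S <- laplace_sources(4, 4000, seed = 31)
  A <- matrix(rnorm(24), 6, 4)
  red <- center_and_whiten(A %*% S, 4)
  f <- infomax(red$Y, seed = 2)
  C <- stats::cor(t(f$W %*% red$Y))
  expect_lt(max(abs(C[upper.tri(C)])), 1e-2)
})

test_that("amari index is zero iff scaled permutation, one for all-ones", {
  expect_equal(amari_index(diag(4)), 0)
  P <- diag(c(2, -3, 0.5))[c(2, 3, 1), ]
  expect_equal(amari_index(P), 0)
  expect_equal(amari_index(matrix(1, 2, 2)), 1)
  expect_gt(amari_index(matrix(c(1, 0.5, 0, 1), 2, 2)), 0)
  expect_error(amari_index(matrix(c(1, 0, 0, 0), 2, 2)), "all-zero")
})

test_that("decomposition satisfies its algebraic and canonical-form contract", {
  S <- laplace_sources(3, 3000, seed = 41)
  A <- matrix(rnorm(30), 10, 3)
  X <- A %*% S + 5
  d <- decompose_networks(X, K = 3, seed = 7)
  expect_lt(reconstruction_error(d), 1e-6)
  # unit variance, zero mean, non-negative skewness per source row
  expect_equal(apply(d$sources, 1, mean), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(d$sources, 1, stats::sd), rep(1, 3), tolerance = 1e-10)
  expect_true(all(apply(d$sources, 1, sbmica:::skewness) >= 0))
  # explained variance ordering
  ev <- d$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  # flipping a source and its mixing column leaves reconstruction unchanged
  d2 <- d
  d2$sources[1, ] <- -d2$sources[1, ]
  d2$mixing[, 1] <- -d2$mixing[, 1]
  expect_equal(d2$mixing %*% d2$sources, d$mixing %*% d$sources,
               tolerance = 1e-12)
})

test_that("gaussian sources are flagged as unidentifiable (no convergence)", {
  set.seed(51)
  Y <- center_and_whiten(matrix(rnorm(6 * 4000), 6, 4000), 2)$Y
  expect_warning(f <- infomax(Y, max_iter = 64, seed = 1), "did not reach")
  expect_false(f$converged)
})
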