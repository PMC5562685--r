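test_that("sources are standardized, deterministic and decorrelated", {
  g <- volume_grid(c(24, 28, 24), 3,
                   mask = default_grid()$mask)
  S <- make_sources(g, K = 4, seed = 7)
  expect_equal(dim(S), c(4L, g$n_voxels))
  expect_true(all(abs(rowMeans(S)) < 1e-10))
  expect_true(all(abs(rowMeans(S^2) - 1) < 1e-10))
  expect_identical(S, make_sources(g, K = 4, seed = 7))

  # brute-force pairwise correlations for K = 6 stay under the ceiling
  S6 <- make_sources(g, K = 6, seed = 11, max_cor = 0.3, max_tries = 50)
  for (a in 1:5) for (b in (a + 1):6) {
    expect_lt(abs(stats::cor(S6[a, ], S6[b, ])), 0.3)
  }
})

test_that("impossible blob geometry is a configuration error", {
  g <- tiny_grid(c(6, 6, 6), 1)  # 6 mm extent
  expect_error(make_sources(g, K = 2, radius_range_mm = c(10, 12), seed = 1),
               "impossible geometry")
})

test_that("cohort sampling honours bins, ratios and determinism", {
  coh <- sample_cohort(seed = 3)
  expect_equal(nrow(coh), 536L)
  expect_equal(levels(coh$site), paste0("site", 1:3))
  expect_true(all(coh$age >= 20 & coh$age <= 86))
  expect_identical(coh, sample_cohort(seed = 3))

  # degenerate single-point bin
  deg <- sample_cohort(10, data.frame(lower = 20, upper = 20, count = 10),
                       seed = 1)
  expect_true(all(deg$age == 20))

  # sex fraction within 3 binomial SDs of the target at large n
  big <- sample_cohort(10000, data.frame(lower = 20, upper = 86,
                                         count = 10000),
                       sex_ratio = 0.5, seed = 5)
  frac <- mean(big$sex == "F")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(
    sample_cohort(50, data.frame(lower = 20, upper = 86, count = 40)),
    "sum to n"
  )
})

test_that("synthesize reproduces the noise-free mixture exactly", {
  g <- tiny_grid()
  specs <- list(loading_spec(1, intercept = 0.7, age = 0, noise_sd = 0),
                loading_spec(1, intercept = 0, age = 0, noise_sd = 0))
  gt <- ground_truth(g, K = 2, loading_specs = specs,
                     site_effect_sd = 0, sex_effect_sd = 0,
                     residual_noise_sd = 0, baseline = 2, seed = 4)
  coh <- quick_cohort(12, seed = 2)
  X <- synthesize(gt, coh)
  expect_equal(dim(X$values), c(12L, g$n_voxels))
  for (i in 1:12) {
    expect_equal(X$values[i, ], 0.7 * gt$sources[1, ] + 2, tolerance = 1e-12)
  }
})

test_that("noise-free linear loadings give the hand-computed row difference", {
  g <- tiny_grid()
  specs <- list(loading_spec(1, intercept = 1, age = -0.005, noise_sd = 0),
                loading_spec(1, intercept = 0, age = 0, noise_sd = 0))
  gt <- ground_truth(g, K = 2, loading_specs = specs, site_effect_sd = 0,
                     sex_effect_sd = 0, residual_noise_sd = 0, seed = 9)
  ages <- c(20, 80, rep(50, 8))
  coh <- quick_cohort(10, seed = 1)
  coh$age <- ages
  coh$site <- factor(rep("site1", 10), levels = levels(coh$site))
  coh$sex <- factor(rep("F", 10), levels = levels(coh$sex))
  X <- synthesize(gt, coh)
  diff <- X$values[1, ] - X$values[2, ]
  expect_equal(diff, 0.3 * gt$sources[1, ], tolerance = 1e-12)
})

test_that("synthesis is affine in the loadings and deterministic", {
  g <- tiny_grid()
  mk <- function(scale) {
    specs <- list(
      loading_spec(1, intercept = scale * 1.0, age = scale * -0.01,
                   noise_sd = 0),
      loading_spec(1, intercept = scale * 0.5, age = scale * 0.02,
                   noise_sd = 0)
    )
    gt <- ground_truth(g, K = 2, loading_specs = specs, site_effect_sd = 0,
                       sex_effect_sd = 0, residual_noise_sd = 0,
                       baseline = 0, seed = 21)
    synthesize(gt, quick_cohort(20, seed = 8))$values
  }
  X1 <- mk(1)
  X2 <- mk(2)
  expect_equal(X2, 2 * X1, tolerance = 1e-10)
  expect_identical(mk(1), X1)
})

test_that("noise-free centred data has numerical rank exactly K", {
  g <- tiny_grid()
  gt <- ground_truth(g, K = 3, loading_specs = default_loading_specs()[1:3],
                     site_effect_sd = 0, sex_effect_sd = 0,
                     residual_noise_sd = 0, seed = 13)
  X <- synthesize(gt, quick_cohort(40, seed = 5))
  Xc <- sweep(X$values, 2, colMeans(X$values))
  d <- svd(Xc, nu = 0, nv = 0)$d
  expect_gt(d[3] / d[1], 1e-8)   # three genuine directions
  expect_lt(d[4] / d[1], 1e-10)  # and nothing beyond
})
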