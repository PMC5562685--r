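test_that("exact fits are reproduced coefficient-for-coefficient", {
  ages <- seq(20, 86, length.out = 30)
  y <- 3 - 0.2 * ages
  f <- fit_polynomial(y, ages, 1)
  expect_equal(unname(f$coefficients), c(3, -0.2), tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)
  expect_equal(f$r2, 1)
  # order 3 on 4 distinct points interpolates perfectly
  f3 <- fit_polynomial(c(1, 5, 2, 7), c(20, 35, 50, 70), 3)
  expect_equal(f3$rss, 0, tolerance = 1e-16)
  expect_equal(f3$bic, -Inf)
})

test_that("degenerate designs raise informative errors", {
  expect_error(fit_polynomial(1:2, c(20, 30), 2), "need n >=")
  expect_error(fit_polynomial(rep(1, 10), rep(50, 10), 1), "all be equal")
  expect_error(fit_polynomial(rnorm(10), rep(c(20, 60), 5), 2), "collinear")
})

test_that("highest-order coefficient is invariant to the age basis", {
  set.seed(101)
  ages <- runif(100, 20, 86)
  y <- 0.5 - 0.01 * ages + 2e-4 * ages^2 + rnorm(100, 0, 0.1)
  f <- fit_polynomial(y, ages, 2)
  raw <- lm(y ~ ages + I(ages^2))
  expect_equal(f$beta_high, unname(coef(raw)[3]), tolerance = 1e-8)
  expect_equal(f$se_high, unname(sqrt(diag(vcov(raw)))[3]), tolerance = 1e-8)
  expect_equal(unname(f$coefficients), unname(coef(raw)), tolerance = 1e-6)
})

test_that("bic follows its closed form and penalty arithmetic", {
  expect_equal(bic(100, 100, 1), 2 * log(100))
  expect_equal(bic(100, 100, 1), 9.2103, tolerance = 1e-4)
  expect_equal(bic(50, 100, 1) - bic(50, 100, 2), -log(100))
  expect_equal(bic(0, 100, 3), -Inf)
  expect_error(bic(-1, 100, 1))
})

test_that("R-squared is non-decreasing in polynomial order", {
  set.seed(102)
  ages <- runif(80, 20, 86)
  y <- 1 - 0.02 * ages + rnorm(80, 0, 0.3)
  r2 <- vapply(1:3, function(o) fit_polynomial(y, ages, o)$r2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("null slope t-test is calibrated at the nominal level", {
  set.seed(103)
  ages <- runif(500, 20, 86)
  design_qr <- qr(cbind(1, ages - mean(ages)))
  n_sim <- 1000
  Y <- matrix(rnorm(500 * n_sim), 500, n_sim)
  hits <- 0
  for (j in seq_len(n_sim)) {
    f <- fit_polynomial(Y[, j], ages, 1)
    t_stat <- f$beta_high / f$se_high
    if (2 * pt(-abs(t_stat), f$df) < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.03)
  expect_lte(hits / n_sim, 0.07)
})

test_that("BIC selects the quadratic order for strong quadratic signals", {
  correct <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    ages <- runif(500, 20, 86)
    trend <- -4e-4 * (ages - 50)^2
    y <- trend + rnorm(500, 0, sd(trend) / 3)  # SNR 3
    fits <- lapply(1:3, function(o) fit_polynomial(y, ages, o))
    sel <- select_and_test(fits, m = 20)
    if (sel$selected_order == 2) correct <- correct + 1
  }
  expect_gte(correct / 20, 0.9)
})

test_that("selection, testing and thresholds follow the published design", {
  # Bonferroni threshold for a 20-component family
  ages <- runif(100, 20, 86)
  set.seed(104)
  y <- rnorm(100)
  fits <- lapply(1:3, function(o) fit_polynomial(y, ages, o))
  sel <- select_and_test(fits, alpha = 0.05, m = 20)
  expect_equal(sel$p_threshold, 2.5e-3)
  expect_identical(sel$significant, sel$p < 2.5e-3)
  # BIC ties break toward the lower order
  f1 <- list(order = 1L, bic = 5, beta_high = 1, se_high = 1, df = 10,
             r2 = 0.5, n = 13, rss = 1)
  f2 <- list(order = 2L, bic = 5, beta_high = 1, se_high = 1, df = 9,
             r2 = 0.5, n = 13, rss = 1)
  expect_equal(select_and_test(list(f1, f2))$selected_order, 1L)
  # t = 0 gives p = 1 exactly
  f0 <- list(order = 1L, bic = 0, beta_high = 0, se_high = 1, df = 10,
             r2 = 0, n = 13, rss = 1)
  expect_equal(select_and_test(list(f0))$p, 1)
})

test_that("extreme t statistics keep exact tiny p-values", {
  f <- list(order = 1L, bic = 0, beta_high = -22.17, se_high = 1, df = 534,
            r2 = 0.479, n = 536, rss = 1)
  sel <- select_and_test(list(f))
  expect_equal(sel$t, -22.17)
  expect_gt(sel$p, 0)
  expect_equal(sel$p, 1.0702e-77, tolerance = 1e-3)
})

test_that("linear-fit identity t^2 = R^2 (n-2)/(1-R^2) holds on all fits", {
  set.seed(105)
  for (rep in 1:10) {
    ages <- runif(50, 20, 86)
    y <- rnorm(50) - 0.01 * ages
    f <- fit_polynomial(y, ages, 1)
    t_stat <- f$beta_high / f$se_high
    expect_equal(abs(t_stat), t_from_r2(f$r2, f$n), tolerance = 1e-8)
  }
})

test_that("CI round-trips through se_from_ci bitwise-close", {
  set.seed(106)
  ages <- runif(60, 20, 86)
  y <- 2 - 0.03 * ages + rnorm(60, 0, 0.2)
  fits <- lapply(1:3, function(o) fit_polynomial(y, ages, o))
  sel <- select_and_test(fits)
  se_back <- se_from_ci(sel$ci[1], sel$ci[2], sel$df)
  expect_equal(se_back, sel$se, tolerance = 1e-12)
  expect_true(sel$ci[1] < sel$beta_high && sel$beta_high < sel$ci[2])
})

test_that("Bonferroni control holds for fixed-order linear tests", {
  # selection-free check of the correction itself: 20 null linear slopes
  # per family, each tested at alpha/20 (BIC selection adds a documented
  # extra multiplicity that the acceptance suite quantifies separately)
  set.seed(107)
  ages <- sample_cohort(seed = 108)$age
  n <- length(ages)
  fams <- 400
  hits <- 0
  for (fam in seq_len(fams)) {
    Y <- matrix(rnorm(n * 20), n, 20)
    ta <- trajectory_analysis(Y, ages, orders = 1, m = 20)
    if (any(ta$report$significant)) hits <- hits + 1
  }
  fwe <- hits / fams
  expect_lte(fwe, 0.05 + 2 * sqrt(0.05 * 0.95 / fams))
})

test_that("age-range restriction behaves like the full design at the bound", {
  set.seed(109)
  coh <- quick_cohort(150, seed = 110)
  W <- cbind(5 - 0.05 * coh$age + rnorm(150, 0, 0.2),
             -3e-4 * (coh$age - 50)^2 + rnorm(150, 0, 0.05))
  full <- trajectory_analysis(W, coh$age, m = 2)
  sens <- age_subset_analysis(W, coh, upper_bounds = c(80, 70, 60), m = 2)
  top <- sens[sens$upper_bound == max(coh$age), ]
  expect_equal(top$t, full$report$t, tolerance = 1e-12)
  expect_equal(top$selected_order, full$report$selected_order)
  # n strictly decreases as the bound drops
  ns <- unique(sens[, c("upper_bound", "n")])
  expect_true(all(diff(ns$n[order(-ns$upper_bound)]) < 0))
})

test_that("linear components stay linear under range restriction", {
  keep <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    coh <- quick_cohort(200, seed = 300 + s)
    trend <- 4 - 0.05 * coh$age
    W <- matrix(trend + rnorm(200, 0, sd(trend - mean(trend)) / 3), ncol = 1)
    sens <- age_subset_analysis(W, coh, upper_bounds = c(80, 70, 60), m = 1)
    if (all(sens$selected_order == 1)) keep <- keep + 1
  }
  expect_gte(keep / 10, 0.9)
})

test_that("range restriction to 60 weakens the quadratic term's t", {
  weaker <- 0
  for (s in 1:20) {
    coh <- quick_cohort(250, seed = 400 + s)
    set.seed(500 + s)
    trend <- -4e-4 * (coh$age - 50)^2
    W <- matrix(trend + rnorm(250, 0, sd(trend) / 3), ncol = 1)
    full_t <- abs(fit_polynomial(W[, 1], coh$age, 2)$beta_high /
                    fit_polynomial(W[, 1], coh$age, 2)$se_high)
    keep <- coh$age <= 60
    f60 <- fit_polynomial(W[keep, 1], coh$age[keep], 2)
    if (abs(f60$beta_high / f60$se_high) < full_t) weaker <- weaker + 1
  }
  expect_gte(weaker / 20, 0.8)
})
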