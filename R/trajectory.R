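#' Fit a polynomial age model to one component's weights
#'
#' OLS on powers of mean-centred age (for numerical conditioning), with
#' coefficients reported after back-transformation to the raw-age basis. The
#' highest-order coefficient and its standard error are identical in both
#' bases, so the downstream t-test is basis-invariant.
#'
#' @param weights per-subject ICA weights (response).
#' @param ages ages in years (predictor).
#' @param order polynomial order, 1, 2 or 3.
#' @return List: `order`, `coefficients` (raw basis, intercept first),
#'   `beta_high`, `se_high`, `rss`, `r2`, `bic`, `n`, `df`.
#' @examples
#' f <- fit_polynomial(3 - 0.2 * (20:60), 20:60, 1)
#' f$coefficients  # (3, -0.2)
#' @export
fit_polynomial <- function(weights, ages, order) {
  order <- as.integer(order)
  stopifnot(order %in% 1:3)
  n <- length(weights)
  if (length(ages) != n) stop("weights and ages must have equal length")
  if (n < order + 1) {
    stop("need n >= order + 1 (got n = ", n, ", order = ", order, ")")
  }
  if (length(unique(ages)) < 2) stop("ages must not all be equal")
  m <- mean(ages)
  xc <- ages - m
  design <- outer(xc, 0:order, `^`)
  qrd <- qr(design)
  if (qrd$rank < order + 1) {
    stop("collinear polynomial design: ", length(unique(ages)),
         " distinct ages cannot support order ", order)
  }
  beta_c <- qr.coef(qrd, weights)
  res <- qr.resid(qrd, weights)
  rss <- sum(res^2)
  tss <- sum((weights - mean(weights))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df <- n - (order + 1L)
  sigma2 <- if (df > 0) rss / df else NaN  # saturated fit: SE undefined
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se_c <- sqrt(sigma2 * diag(xtx_inv))
  # back-transform: (x - m)^k = sum_j choose(k, j) (-m)^(k - j) x^j
  Tm <- outer(0:order, 0:order, function(k, j) {
    ifelse(j <= k, choose(k, j) * (-m)^(k - j), 0)
  })
  beta_raw <- as.numeric(crossprod(Tm, beta_c))
  names(beta_raw) <- paste0("age^", 0:order)
  list(order = order, coefficients = beta_raw,
       beta_high = beta_raw[[order + 1L]], se_high = se_c[order + 1L],
       rss = rss, r2 = r2, bic = bic(rss, n, order), n = n, df = df)
}

#' Bayesian Information Criterion for a polynomial regression
#'
#' `BIC = n * ln(RSS/n) + (order + 1) * ln(n)`, counting the regression
#' coefficients as free parameters (the error variance would add the same
#' `ln(n)` to every model and cannot change rankings). A perfect fit
#' (`RSS = 0`) returns `-Inf` so saturated models win any comparison but lose
#' ties to lower orders by the tie-break in [select_and_test()].
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations (`n > order + 1`).
#' @param order polynomial order.
#' @return Scalar BIC.
#' @examples
#' bic(100, 100, 1)  # 2 * log(100) = 9.2103
#' @export
bic <- function(rss, n, order) {
  stopifnot(rss >= 0, n >= order + 1)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + (order + 1) * log(n)
}

#' Select the trajectory order by BIC and test its top coefficient
#'
#' The selected order minimises BIC (ties, including the degenerate
#' `RSS = 0` case, break toward the lower order — parsimony). A two-sided
#' single-sample t-test is applied to the selected model's highest-order age
#' coefficient: `t = beta_high / SE`, `df = n - (order + 1)`, with the
#' p-value from the t distribution's survival function (accurate in double
#' precision down to magnitudes around 1e-300, so values like 1e-77 are
#' exact, never flushed to zero). Significance is declared at the
#' Bonferroni-corrected level `alpha / m`.
#'
#' @param fits list of [fit_polynomial()] records for orders 1-3, in order.
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of tests in the family (default 20, the component count).
#' @return Object of class `trajectory_fit`: the per-order records plus
#'   `selected_order`, `beta_high`, `se`, `ci` (95%), `t`, `df`, `p`,
#'   `p_threshold`, `significant`, `n`.
#' @export
select_and_test <- function(fits, alpha = 0.05, m = 20L) {
  stopifnot(length(fits) >= 1)
  orders <- vapply(fits, `[[`, integer(1), "order")
  stopifnot(!is.unsorted(orders))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- which.min(bics)  # first minimum = lowest order on ties
  f <- fits[[sel]]
  t_stat <- if (f$se_high == 0) {
    if (f$beta_high == 0) 0 else sign(f$beta_high) * Inf
  } else {
    f$beta_high / f$se_high
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), f$df)
  q <- stats::qt(0.975, f$df)
  structure(
    list(fits = fits, selected_order = f$order, beta_high = f$beta_high,
         se = f$se_high, ci = c(f$beta_high - q * f$se_high,
                                f$beta_high + q * f$se_high),
         r2 = f$r2, t = t_stat, df = f$df, p = p,
         p_threshold = alpha / m, significant = p < alpha / m, n = f$n),
    class = "trajectory_fit"
  )
}

#' Age-trajectory analysis of every component's ICA weights
#'
#' Fits linear, quadratic and cubic age models per component, selects by BIC
#' and tests the highest-order coefficient with Bonferroni correction
#' (default `m` = number of components).
#'
#' @param mixing n x K mixing matrix (or `sbm_decomposition`).
#' @param ages ages in years aligned to rows.
#' @param orders polynomial orders to fit (default 1:3).
#' @param alpha family-wise level.
#' @param m number of Bonferroni tests (default `ncol(mixing)`).
#' @return Object of class `trajectory_analysis`: list `fits` of
#'   [select_and_test()] results and a tidy `report` data.frame (one row per
#'   component: selected order, per-order BICs, R^2, beta and CI, t, df, p,
#'   threshold, significance).
#' @export
trajectory_analysis <- function(mixing, ages, orders = 1:3, alpha = 0.05,
                                m = NULL) {
  if (inherits(mixing, "sbm_decomposition")) mixing <- mixing$mixing
  mixing <- as.matrix(mixing)
  K <- ncol(mixing)
  m <- m %||% K
  fits <- lapply(seq_len(K), function(k) {
    per_order <- lapply(orders, function(o) {
      fit_polynomial(mixing[, k], ages, o)
    })
    select_and_test(per_order, alpha = alpha, m = m)
  })
  report <- do.call(rbind, lapply(seq_len(K), function(k) {
    f <- fits[[k]]
    row <- data.frame(
      component = k, selected_order = f$selected_order,
      r2 = f$r2, beta_high = f$beta_high, ci_low = f$ci[1], ci_high = f$ci[2],
      t = f$t, df = f$df, p = f$p, p_bonf_threshold = f$p_threshold,
      significant = f$significant
    )
    for (i in seq_along(orders)) {
      row[[paste0("bic_order", orders[i])]] <- f$fits[[i]]$bic
    }
    row
  }))
  structure(list(fits = fits, report = report, alpha = alpha, m = m),
            class = "trajectory_analysis")
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat(sprintf("trajectory_analysis: %d components, %d significant at p < %g\n",
              nrow(x$report), sum(x$report$significant),
              x$alpha / x$m))
  print(x$report[, c("component", "selected_order", "r2", "beta_high",
                     "t", "p", "significant")], digits = 4)
  invisible(x)
}

#' Age-range sensitivity analysis
#'
#' Repeats the full BIC-selection-plus-test per component on age-restricted
#' subsets of the cohort. The ICA weights stay fixed from the full-cohort
#' decomposition; only subjects are subset by age, so the analysis isolates
#' the effect of range restriction on the fitted trajectories.
#'
#' @param mixing n x K mixing matrix (or `sbm_decomposition`).
#' @param cohort covariate table aligned to rows (needs `age`).
#' @param upper_bounds upper age bounds for the subsets (default 80, 70, 60);
#'   the full range is always included as the first row block.
#' @param orders,alpha,m as in [trajectory_analysis()].
#' @return A data.frame of class `sbm_sensitivity`: one row per
#'   (age range x component) with `upper_bound`, `n`, `component`,
#'   `selected_order`, `t`, `p`, `significant`.
#' @export
age_subset_analysis <- function(mixing, cohort, upper_bounds = c(80, 70, 60),
                                orders = 1:3, alpha = 0.05, m = NULL) {
  if (inherits(mixing, "sbm_decomposition")) mixing <- mixing$mixing
  mixing <- as.matrix(mixing)
  stopifnot(nrow(mixing) == nrow(cohort))
  bounds <- c(max(cohort$age), upper_bounds)
  out <- list()
  for (b in bounds) {
    keep <- cohort$age <= b
    if (!any(keep)) {
      warning("no subjects at or below age ", b, "; subset skipped")
      next
    }
    if (sum(keep) <= 10) {
      warning("subset age <= ", b, " retains only ", sum(keep),
              " subjects; skipped")
      next
    }
    ta <- trajectory_analysis(mixing[keep, , drop = FALSE],
                              cohort$age[keep], orders = orders,
                              alpha = alpha, m = m)
    out[[length(out) + 1L]] <- data.frame(
      upper_bound = b, n = sum(keep),
      ta$report[, c("component", "selected_order", "t", "p", "significant")]
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("sbm_sensitivity", "data.frame")
  out
}
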