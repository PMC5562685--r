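#' Absolute t statistic implied by a linear fit's R-squared
#'
#' For a simple linear regression, `t^2 = R^2 (n - 2) / (1 - R^2)` exactly.
#' Used to validate fitted models against their own t statistics and to
#' consistency-check published regression tables that print R^2 and t side
#' by side.
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @param n number of observations (> 2).
#' @return `|t|`; `Inf` when `r2 == 1`.
#' @examples
#' t_from_r2(0.306, 536)  # 15.34
#' @export
t_from_r2 <- function(r2, n) {
  stopifnot(r2 >= 0, r2 <= 1, n > 2)
  if (r2 == 1) return(Inf)
  sqrt(r2 * (n - 2) / (1 - r2))
}

#' Standard error implied by a 95% confidence interval
#'
#' `SE = (hi - lo) / (2 q)` with `q` the 97.5% quantile of the t
#' distribution on `df` degrees of freedom.
#'
#' @param lo,hi confidence bounds (`lo < hi`).
#' @param df residual degrees of freedom (>= 1).
#' @return The implied standard error.
#' @export
se_from_ci <- function(lo, hi, df) {
  stopifnot(df >= 1)
  if (lo >= hi) stop("confidence bounds must satisfy lo < hi")
  (hi - lo) / (2 * stats::qt(0.975, df))
}

#' t statistic implied by a coefficient and its 95% confidence interval
#'
#' @param beta point estimate.
#' @param lo,hi confidence bounds (`lo < hi`).
#' @param df residual degrees of freedom.
#' @return `beta / se_from_ci(lo, hi, df)`.
#' @examples
#' t_from_beta_ci(-3.92e-4, -4.85e-4, -2.98e-4, 534)  # -8.24
#' @export
t_from_beta_ci <- function(beta, lo, hi, df) {
  beta / se_from_ci(lo, hi, df)
}

#' Consistency-check a trajectory report table
#'
#' Validates the internal statistical identities of a regression table (own
#' output or a transcribed published table): for every linear
#' (`selected_order == 1`) row, the printed t must agree with the t implied
#' by R^2 (within `tol_t`, default 0.03 for 2-decimal tables) and with the t
#' implied by beta and its 95% CI. The CI check uses
#' `max(tol_t, tol_ci_rel * |t|)` because bounds printed to 3 significant
#' figures can perturb the CI width — hence the implied t — by about 1%.
#' Every row's p is checked against the two-sided t-distribution p at the
#' printed t (relative tolerance `tol_p_rel`, covering rounding of t).
#'
#' @param table a data.frame or TSV path with columns `component`,
#'   `selected_order`, `r2`, `beta_high`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p`.
#' @param tol_t absolute tolerance for the t-from-R^2 check.
#' @param tol_ci_rel relative component of the t-from-CI tolerance.
#' @param tol_p_rel relative tolerance for the p check.
#' @return A data.frame with per-row logical columns `t_r2_ok`, `t_ci_ok`,
#'   `p_ok` and `all_ok`; malformed rows are reported with `NA` checks.
#'   Attribute `consistent` is `TRUE` when every checked row passes (an
#'   empty table is trivially consistent).
#' @export
validate_report <- function(table, tol_t = 0.03, tol_ci_rel = 0.01,
                            tol_p_rel = 0.10) {
  if (is.character(table)) table <- utils::read.delim(table)
  need <- c("component", "selected_order", "r2", "beta_high", "ci_low",
            "ci_high", "t", "df", "p")
  if (!all(need %in% names(table))) {
    stop("report must have columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    out <- data.frame(component = r$component, t_r2_ok = NA, t_ci_ok = NA,
                      p_ok = NA)
    malformed <- !all(is.finite(c(r$r2, r$beta_high, r$ci_low, r$ci_high,
                                  r$t, r$df, r$p))) || r$ci_low >= r$ci_high
    if (malformed) return(out)
    if (r$selected_order == 1) {
      t_r2 <- sign(r$beta_high) * t_from_r2(r$r2, r$df + 2)
      out$t_r2_ok <- abs(t_r2 - r$t) <= tol_t
      t_ci <- t_from_beta_ci(r$beta_high, r$ci_low, r$ci_high, r$df)
      out$t_ci_ok <- abs(t_ci - r$t) <= max(tol_t, tol_ci_rel * abs(r$t))
    }
    p_t <- 2 * stats::pt(-abs(r$t), r$df)
    out$p_ok <- abs(p_t - r$p) <= tol_p_rel * r$p
    out
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(component = numeric(0), t_r2_ok = logical(0),
               t_ci_ok = logical(0), p_ok = logical(0))
  )))
  out$all_ok <- vapply(seq_len(nrow(out)), function(i) {
    v <- unlist(out[i, c("t_r2_ok", "t_ci_ok", "p_ok")])
    all(v[!is.na(v)])
  }, logical(1))
  attr(out, "consistent") <- all(out$all_ok)
  out
}
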