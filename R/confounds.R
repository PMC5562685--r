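#' Build the scanner/sex confound design matrix
#'
#' Intercept + (L-1) site indicator columns (reference coding against the
#' first observed site level) + one sex indicator (second level coded 1).
#' Indicator columns for levels with no subjects are dropped with a message,
#' keeping the design full rank. The residuals produced downstream are
#' invariant to the choice of full-rank coding, which is why a reference
#' coding is used even though site could equivalently be coded with one
#' column per scanner.
#'
#' @param cohort an [sample_cohort()]-style covariate table with `site` and
#'   `sex` factors.
#' @param coding `"reference"` (default) or `"sum"` site coding; both span
#'   the same column space.
#' @return An object of class `confound_design`: list with `matrix` (n x p,
#'   full column rank), `coding`, and `columns` (names).
#' @export
build_confound_design <- function(cohort, coding = c("reference", "sum")) {
  coding <- match.arg(coding)
  n <- nrow(cohort)
  site <- droplevels(factor(cohort$site))
  sex <- droplevels(factor(cohort$sex))
  M <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  L <- nlevels(site)
  if (L >= 2) {
    if (coding == "reference") {
      for (lev in levels(site)[-1]) {
        M <- cbind(M, as.numeric(site == lev))
        colnames(M)[ncol(M)] <- paste0("site_", lev)
      }
    } else {
      # sum coding: last level coded -1 on every site column
      for (lev in levels(site)[-L]) {
        col <- as.numeric(site == lev) - as.numeric(site == levels(site)[L])
        M <- cbind(M, col)
        colnames(M)[ncol(M)] <- paste0("site_sum_", lev)
      }
    }
  } else {
    message("only one site level present; site columns dropped")
  }
  if (nlevels(sex) >= 2) {
    M <- cbind(M, as.numeric(sex == levels(sex)[2]))
    colnames(M)[ncol(M)] <- paste0("sex_", levels(sex)[2])
  } else {
    message("only one sex level present; sex column dropped")
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = M, coding = coding, columns = colnames(M)),
            class = "confound_design")
}

#' Remove scanner/sex confounds from every voxel
#'
#' Per voxel, the values are replaced by the OLS residuals of a regression on
#' the confound design, with the voxel's grand mean added back so the matrix
#' keeps its gray-matter-like positive scale (the decomposition re-centres
#' internally, so the added-back mean is inconsequential to the ICA). The
#' residual component is orthogonal to every design column.
#'
#' @param X an [data_matrix()] (or plain matrix).
#' @param design a [build_confound_design()] object, or `NULL` to build the
#'   reference-coded design from `X$cohort`.
#' @return Object of the same type as `X` with adjusted values.
#' @export
residualize <- function(X, design = NULL) {
  is_dm <- inherits(X, "sbm_data_matrix")
  vals <- if (is_dm) X$values else as.matrix(X)
  if (is.null(design)) {
    if (!is_dm) stop("a design is required when X is a bare matrix")
    design <- build_confound_design(X$cohort)
  }
  M <- design$matrix
  if (nrow(M) != nrow(vals)) {
    stop("design rows (", nrow(M), ") must align with data rows (",
         nrow(vals), ")")
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrM, vals)
  out <- sweep(res, 2, colMeans(vals), `+`)
  if (is_dm) data_matrix(out, X$grid, X$cohort, loadings = X$loadings) else out
}
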