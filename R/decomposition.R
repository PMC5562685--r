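#' Compose a decomposition from data, whitening operators and unmixing
#'
#' Produces the canonical subject-by-component mixing matrix and
#' component-by-voxel source matrix. Sources are `W %*% Y` rescaled to unit
#' sample variance per row (they inherit exact zero mean over voxels from the
#' whitening); the mixing matrix follows the de-whitening path so that
#' `mixing %*% sources` reproduces the rank-K truncation of the
#' double-centred data to machine precision. Two canonical-form conventions
#' resolve ICA's sign and order ambiguities: each source is flipped so its
#' skewness over voxels is non-negative, and components are sorted by
#' descending explained variance (squared norm of the mixing column).
#'
#' @param X the [data_matrix()] (or matrix) the whitening was computed from.
#' @param reduction an [center_and_whiten()] result.
#' @param W the K x K unmixing matrix (e.g. from [infomax()]).
#' @param convergence optional convergence metadata list to carry along.
#' @param seed optional seed metadata.
#' @return Object of class `sbm_decomposition`: `mixing` (n x K), `sources`
#'   (K x V), `reduction`, `convergence`, `explained_variance`, `seed`.
#' @export
compose_decomposition <- function(X, reduction, W, convergence = NULL,
                                  seed = NULL) {
  Y <- reduction$Y
  K <- nrow(Y)
  stopifnot(identical(dim(W), c(K, K)))
  S_raw <- W %*% Y
  sds <- sqrt(rowMeans(S_raw^2) * ncol(Y) / (ncol(Y) - 1))
  if (any(sds < 1e-12)) {
    stop("zero-variance source row(s): ",
         paste(which(sds < 1e-12), collapse = ", "))
  }
  sources <- S_raw / sds
  mixing <- reduction$dewhiten %*% solve(W) %*% diag(sds, K)
  # sign convention: non-negative source skewness
  sk <- apply(sources, 1, skewness)
  flip <- ifelse(sk < 0, -1, 1)
  sources <- sources * flip
  mixing <- sweep(mixing, 2, flip, `*`)
  # order by descending explained variance (sources have unit variance)
  evar <- colSums(mixing^2)
  ord <- order(evar, decreasing = TRUE)
  structure(
    list(mixing = mixing[, ord, drop = FALSE],
         sources = sources[ord, , drop = FALSE],
         reduction = reduction, convergence = convergence,
         explained_variance = evar[ord], seed = seed),
    class = "sbm_decomposition"
  )
}

#' Decompose a gray-matter data matrix into spatial networks
#'
#' One-call wrapper: [center_and_whiten()] to `K` dimensions, [infomax()] on
#' the whitened matrix, then [compose_decomposition()]. `K = 20` is the
#' pipeline default component count.
#'
#' @param X an [data_matrix()] or plain n x V matrix.
#' @param K number of components.
#' @param seed integer seed for the infomax initialisation.
#' @param ... further arguments to [infomax()] (`lr0`, `max_iter`, `tol`).
#' @return An `sbm_decomposition` (see [compose_decomposition()]).
#' @export
decompose_networks <- function(X, K = 20L, seed = NULL, ...) {
  reduction <- center_and_whiten(X, K)
  fit <- infomax(reduction$Y, seed = seed, ...)
  compose_decomposition(X, reduction, fit$W,
                        convergence = fit[c("iterations", "final_update",
                                            "lr_trace", "converged")],
                        seed = seed)
}

#' @export
print.sbm_decomposition <- function(x, ...) {
  cat(sprintf(
    "sbm_decomposition: %d subjects x %d components x %d voxels (%s)\n",
    nrow(x$mixing), ncol(x$mixing), ncol(x$sources),
    if (isTRUE(x$convergence$converged)) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Reconstruction error of a decomposition
#'
#' Relative Frobenius error of `mixing %*% sources` against the rank-K
#' truncation of the double-centred data it was fitted to; an algebraic
#' identity of the de-whitening path, so values are at machine precision for
#' any converged or unconverged unmixing.
#'
#' @param decomp an `sbm_decomposition`.
#' @return Scalar relative error.
#' @export
reconstruction_error <- function(decomp) {
  target <- decomp$reduction$dewhiten %*% decomp$reduction$Y
  err <- decomp$mixing %*% decomp$sources - target
  sqrt(sum(err^2)) / sqrt(sum(target^2))
}
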