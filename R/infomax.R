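#' Non-extended infomax ICA on whitened data
#'
#' Full-batch natural-gradient infomax with the logistic nonlinearity
#' `g(u) = 1/(1 + exp(-u))`, which maximises output entropy (equivalently,
#' minimises mutual information among the sources) and whose separating
#' solution is stable for super-Gaussian sources. The update rule is
#'
#' `dW = lr * (I + (1 - 2 g(U)) U^T / V) W`, with `U = W Y`.
#'
#' The learning rate is annealed: when the angle between successive updates
#' exceeds 60 degrees the rate is halved (oscillation indicates overshoot).
#' Iteration stops when `||dW||_F / ||W||_F < tol` or at `max_iter`, in which
#' case the result carries a non-convergence warning flag rather than an
#' error. The initial unmixing matrix is a random orthonormal matrix drawn
#' from `seed`, so runs are bit-reproducible.
#'
#' Note the classical identifiability caveat: with Gaussian sources any
#' rotation whitens equally well, so the algorithm may return an arbitrary
#' rotation (typically flagged as non-converged).
#'
#' @param Y K x V whitened matrix (rows zero mean, identity covariance).
#' @param lr0 initial learning rate.
#' @param max_iter maximum number of full-batch iterations.
#' @param tol relative update-norm stopping threshold.
#' @param seed integer seed for the orthonormal initialisation.
#' @return List of class `sbm_infomax`: `W` (K x K unmixing matrix),
#'   `iterations`, `final_update` (last relative update norm), `lr_trace`,
#'   `converged` (logical).
#' @export
infomax <- function(Y, lr0 = 0.1, max_iter = 2048L, tol = 1e-6,
                    seed = NULL) {
  K <- nrow(Y)
  V <- ncol(Y)
  W <- with_seed(seed, qr.Q(qr(matrix(rnorm(K * K), K, K))))
  lr <- lr0
  lr_trace <- numeric(0)
  prev_dW <- NULL
  final_update <- Inf
  iterations <- 0L
  converged <- FALSE
  I_K <- diag(K)
  for (it in seq_len(max_iter)) {
    iterations <- it
    U <- W %*% Y
    G <- 1 / (1 + exp(-U))
    grad <- (I_K + (1 - 2 * G) %*% t(U) / V)
    dW <- lr * grad %*% W
    if (!is.null(prev_dW)) {
      num <- sum(dW * prev_dW)
      den <- sqrt(sum(dW^2)) * sqrt(sum(prev_dW^2))
      if (den > 0 && num / den < cos(pi / 3)) lr <- lr / 2
    }
    lr_trace <- c(lr_trace, lr)
    W <- W + dW
    prev_dW <- dW
    final_update <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    if (!all(is.finite(W))) {
      stop("infomax diverged (non-finite unmixing matrix); lower lr0")
    }
    if (final_update < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("infomax did not reach tol = ", tol, " in ", max_iter,
            " iterations (final relative update ",
            signif(final_update, 3), ")")
  }
  structure(
    list(W = W, iterations = iterations, final_update = final_update,
         lr_trace = lr_trace, converged = converged),
    class = "sbm_infomax"
  )
}

#' Amari performance index of a (near-)permutation matrix
#'
#' The standard blind-source-separation quality metric for `P = W_est %*% A`
#' (or any square comparison matrix): zero if and only if `P` is a scaled
#' permutation. Normalised by `2 K (K - 1)` so the index lies in `[0, 1]`;
#' the K x K all-ones matrix attains the maximum 1.
#'
#' @param P square numeric matrix with no all-zero row or column.
#' @return Scalar index in `[0, 1]`.
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  K <- nrow(P)
  stopifnot(ncol(P) == K)
  rmax <- apply(P, 1, max)
  cmax <- apply(P, 2, max)
  if (any(rmax == 0) || any(cmax == 0)) {
    stop("Amari index undefined for a matrix with an all-zero row or column")
  }
  rows <- sum(rowSums(P / rmax) - 1)
  cols <- sum(colSums(t(t(P) / cmax)) - 1)
  (rows + cols) / (2 * K * (K - 1))
}

#' Exhaustive-rotation kurtosis oracle for two-source ICA
#'
#' Independent reference unmixing for K = 2 whitened data: scans rotation
#' angles in `[0, pi)` in steps of `step_deg` degrees and returns the
#' rotation maximising the summed absolute excess kurtosis of the two rotated
#' rows. Used to cross-check [infomax()] on toy problems.
#'
#' @param Y 2 x V whitened matrix.
#' @param step_deg angular step in degrees.
#' @return List: `W` (2 x 2 rotation), `theta` (radians), `objective`.
#' @export
rotation_kurtosis_oracle <- function(Y, step_deg = 0.1) {
  stopifnot(nrow(Y) == 2)
  thetas <- seq(0, pi, by = step_deg * pi / 180)
  thetas <- thetas[thetas < pi]
  best <- -Inf
  best_theta <- 0
  for (th in thetas) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    S <- R %*% Y
    obj <- abs(excess_kurtosis(S[1, ])) + abs(excess_kurtosis(S[2, ]))
    if (obj > best) {
      best <- obj
      best_theta <- th
    }
  }
  R <- matrix(c(cos(best_theta), -sin(best_theta),
                sin(best_theta), cos(best_theta)), 2, 2, byrow = TRUE)
  list(W = R, theta = best_theta, objective = best)
}
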