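#' Centre and whiten a subject-by-voxel matrix for spatial ICA
#'
#' Removes the per-voxel mean across subjects and the per-subject mean across
#' voxels, then projects onto the top `K` principal axes via SVD. Voxels are
#' the ICA samples: the returned `K x n_voxels` matrix has exactly zero row
#' means and identity sample covariance over voxels. The de-whitening
#' operator maps whitened rows back to subject space, so that
#' `dewhiten %*% Y` equals the rank-K truncation of the double-centred data.
#'
#' @param X an [data_matrix()] or plain n x V matrix.
#' @param K number of retained components
#'   (`K <= min(n_subjects - 1, n_voxels)`).
#' @return List of class `sbm_whitened`: `Y` (K x V whitened matrix),
#'   `dewhiten` (n x K), `retained_variance` (fraction of double-centred
#'   variance captured by the top K axes), `voxel_means`, `subject_means`,
#'   `singular_values`.
#' @export
center_and_whiten <- function(X, K) {
  vals <- if (inherits(X, "sbm_data_matrix")) X$values else as.matrix(X)
  n <- nrow(vals)
  V <- ncol(vals)
  if (K > min(n - 1, V)) {
    stop("K = ", K, " exceeds min(n_subjects - 1, n_voxels) = ",
         min(n - 1, V))
  }
  voxel_means <- colMeans(vals)
  Xc <- sweep(vals, 2, voxel_means)
  subject_means <- rowMeans(Xc)
  Xc <- Xc - subject_means
  sv <- svd(Xc, nu = K, nv = K)
  rank_tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  num_rank <- sum(sv$d > rank_tol)
  if (K > num_rank) {
    stop("K = ", K, " exceeds the numerical rank ", num_rank,
         " of the centred data")
  }
  # rows of t(v) have zero mean (double-centred input); scale so that the
  # sample covariance over voxels is exactly the identity
  Y <- t(sv$v) * sqrt(V - 1)
  dewhiten <- sv$u %*% diag(sv$d[seq_len(K)], K) / sqrt(V - 1)
  structure(
    list(Y = Y, dewhiten = dewhiten,
         retained_variance = sum(sv$d[seq_len(K)]^2) / sum(sv$d^2),
         voxel_means = voxel_means, subject_means = subject_means,
         singular_values = sv$d),
    class = "sbm_whitened"
  )
}
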