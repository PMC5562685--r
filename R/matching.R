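# Optimal linear assignment (Hungarian algorithm, O(n^3) potentials form).
# Returns, for each row of the square cost matrix, the assigned column.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  VIRT <- n + 1L  # virtual column playing the role of "column 0"
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[VIRT] <- i
    j0 <- VIRT
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == VIRT) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) assign_row[p[j]] <- j
  assign_row
}

#' Match estimated components to ground-truth sources
#'
#' Finds the one-to-one assignment between estimated and true spatial sources
#' maximising the total absolute Pearson correlation over in-mask voxels
#' (optimal assignment via the Hungarian algorithm, not greedy matching).
#' When component counts differ, the smaller set is matched and the surplus
#' flagged unmatched. Loading correlations compare the matched mixing columns
#' against the realized true loadings when available.
#'
#' @param est an `sbm_decomposition` (or K_est x V source matrix).
#' @param truth an [ground_truth()] object (or K_true x V source matrix).
#' @param true_loadings optional n x K_true matrix of realized loadings (used
#'   automatically when `est` carries a synthetic [data_matrix()]'s
#'   loadings).
#' @return Object of class `sbm_recovery`: data.frame `pairs` with columns
#'   `est`, `truth`, `cor` (absolute spatial correlation), `sign`,
#'   `loading_cor` (may be `NA`), plus `mean_cor` and `unmatched`.
#' @export
match_components <- function(est, truth, true_loadings = NULL) {
  S_est <- if (inherits(est, "sbm_decomposition")) est$sources else
    as.matrix(est)
  S_true <- if (inherits(truth, "sbm_ground_truth")) truth$sources else
    as.matrix(truth)
  if (ncol(S_est) != ncol(S_true)) {
    stop("estimated and true sources must live on the same mask")
  }
  Ke <- nrow(S_est)
  Kt <- nrow(S_true)
  C <- stats::cor(t(S_est), t(S_true))  # Ke x Kt signed correlations
  K <- max(Ke, Kt)
  cost <- matrix(0, K, K)  # padded entries cost 0 (= |cor| 0)
  cost[seq_len(Ke), seq_len(Kt)] <- -abs(C)
  assign_col <- solve_assignment(cost)
  pairs <- data.frame(est = integer(0), truth = integer(0),
                      cor = numeric(0), sign = numeric(0))
  for (i in seq_len(Ke)) {
    j <- assign_col[i]
    if (j <= Kt) {
      pairs <- rbind(pairs, data.frame(
        est = i, truth = j, cor = abs(C[i, j]), sign = sign(C[i, j])
      ))
    }
  }
  pairs <- pairs[order(pairs$truth), , drop = FALSE]
  rownames(pairs) <- NULL
  if (is.null(true_loadings) && inherits(est, "sbm_decomposition")) {
    true_loadings <- attr(est, "true_loadings")
  }
  pairs$loading_cor <- NA_real_
  if (!is.null(true_loadings) && inherits(est, "sbm_decomposition")) {
    for (r in seq_len(nrow(pairs))) {
      pairs$loading_cor[r] <- abs(stats::cor(
        est$mixing[, pairs$est[r]], true_loadings[, pairs$truth[r]]
      ))
    }
  }
  structure(
    list(pairs = pairs, mean_cor = mean(pairs$cor),
         unmatched = list(est = setdiff(seq_len(Ke), pairs$est),
                          truth = setdiff(seq_len(Kt), pairs$truth))),
    class = "sbm_recovery"
  )
}

#' @export
print.sbm_recovery <- function(x, ...) {
  cat(sprintf("sbm_recovery: %d matched pairs, mean |cor| = %.3f\n",
              nrow(x$pairs), x$mean_cor))
  print(x$pairs)
  invisible(x)
}
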