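# Shared fixtures, built in code at test time.

tiny_grid <- function(shape = c(10L, 10L, 10L), voxel_size = 3) {
  volume_grid(shape, voxel_size)
}

# Single-bin cohort spanning the full adult range.
quick_cohort <- function(n = 60L, seed = 1L, lower = 20, upper = 86) {
  sample_cohort(n, data.frame(lower = lower, upper = upper, count = n),
                seed = seed)
}

# Blob sources sized for a small test grid (the default radii suit the
# full-scale analysis grid).
tiny_sources <- function(grid, K, seed, ...) {
  make_sources(grid, K, seed = seed, radius_range_mm = c(3, 5), ...)
}

# Unit-variance Laplace rows: super-Gaussian toy sources for ICA tests.
laplace_sources <- function(K, V, seed) {
  set.seed(seed)
  S <- matrix(stats::rexp(K * V) * sample(c(-1, 1), K * V, TRUE), K, V)
  S <- S - rowMeans(S)
  S / sqrt(rowMeans(S^2))
}

# Independent flood-fill connected-component oracle (queue-based BFS over
# explicit neighbour offsets), deliberately simpler than the union-find
# implementation it cross-checks.
flood_fill_labels <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  offs <- sbmica:::connectivity_offsets(connectivity)
  lab <- array(0L, dim = d)
  next_label <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    lab[start] <- next_label
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        ni <- co[1] + offs[r, 1]
        nj <- co[2] + offs[r, 2]
        nk <- co[3] + offs[r, 3]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] ||
            nk < 1 || nk > d[3]) next
        lin <- (nk - 1L) * d[1] * d[2] + (nj - 1L) * d[1] + ni
        if (bin[lin] && lab[lin] == 0L) {
          lab[lin] <- next_label
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Canonical partition signature: voxels grouped by label, order-free.
partition_signature <- function(lab) {
  ids <- setdiff(unique(as.integer(lab)), 0L)
  sets <- lapply(ids, function(l) sort(which(lab == l)))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}

# One small end-to-end synthetic run shared by pipeline-level tests.
recovery_run <- function(seed, n = 200L, K = 4L) {
  cfg <- run_config(mode = "synthetic", K = K, n_subjects = n,
                    seed = as.integer(seed),
                    output_dir = tempfile("sbm_test_"))
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
}
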