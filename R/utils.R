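# Internal helpers shared across modules.

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic stream splitting: each pipeline stage draws its randomness
#' from a seed derived from the master seed and a stage label, so stages can
#' be rerun in isolation and still reproduce the full-pipeline output.
#' The label is hashed by summing character codes; the combination is folded
#' into the 31-bit signed integer range accepted by [set.seed()].
#'
#' @param seed integer master seed.
#' @param stage character stage label (e.g. `"sources"`, `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 2147483647 + 104729 * (h %% 20011)) %% 2147483646)
}

# Run expr with a local RNG state seeded by `seed`; the caller's RNG state is
# untouched. `seed = NULL` uses the current stream (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sample skewness (population formula); used for the source sign convention.
skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Excess kurtosis (population formula).
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 == 0) return(0)
  mean(x^4) / s2^2 - 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
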