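#' Generate covariant spatial sources as sums of Gaussian blobs
#'
#' Each source is the sum of 1-4 smooth 3-D Gaussian blobs placed inside the
#' mask, optionally mirrored across the x midline to mimic the bilateral
#' morphology typical of gray-matter covariance networks, then standardized to
#' zero mean / unit variance over in-mask voxels. Blobs on a zero background
#' give sparse, positively skewed, super-Gaussian voxel distributions — the
#' regime the non-extended infomax contrast assumes. Blob centres are
#' resampled until every pair of distinct sources has absolute spatial
#' correlation below `max_cor` and every source has excess kurtosis of at
#' least `min_kurtosis` over the mask (a draw whose blobs flood the mask is
#' no longer sparse — it can even be sub-Gaussian — and would be
#' unrecoverable by the logistic infomax contrast).
#'
#' @param grid a [volume_grid()].
#' @param K number of sources (>= 2).
#' @param blob_count_range length-2 integer range of blobs per source.
#' @param seed integer seed; fully determines the maps.
#' @param radius_range_mm length-2 range of blob Gaussian radii (sigma, mm).
#' @param mirror_prob probability a source is mirrored across the x midline.
#' @param max_cor pairwise absolute-correlation ceiling enforced by
#'   resampling.
#' @param min_kurtosis excess-kurtosis floor (super-Gaussianity) enforced by
#'   resampling.
#' @param max_tries resampling attempts per source before giving up.
#' @return A `K x n_voxels` matrix; rows are standardized in-mask source maps.
#' @export
make_sources <- function(grid, K, blob_count_range = c(1L, 4L), seed = NULL,
                         radius_range_mm = c(4.5, 9), mirror_prob = 0.5,
                         max_cor = 0.15, min_kurtosis = 2, max_tries = 500L) {
  stopifnot(K >= 2)
  extent_mm <- grid$shape * grid$voxel_size
  if (min(radius_range_mm) >= min(extent_mm)) {
    stop("impossible geometry: blob radius ", min(radius_range_mm),
         " mm does not fit inside grid extent ",
         paste(round(extent_mm, 1), collapse = "x"), " mm")
  }
  ijk <- linear_to_ijk(grid, grid$mask_idx)            # 0-based, in-mask
  xyz <- sweep(ijk, 2, grid$voxel_size, `*`)           # scanner-axis mm
  mid_x <- (grid$shape[1] - 1) * grid$voxel_size[1] / 2
  lo <- apply(xyz, 2, min) + 0.15 * (apply(xyz, 2, max) - apply(xyz, 2, min))
  hi <- apply(xyz, 2, max) - 0.15 * (apply(xyz, 2, max) - apply(xyz, 2, min))

  one_source <- function() {
    nb <- sample(seq(blob_count_range[1], blob_count_range[2]), 1L)
    mirrored <- runif(1) < mirror_prob
    v <- numeric(nrow(xyz))
    for (b in seq_len(nb)) {
      ctr <- runif(3, lo, hi)
      r <- runif(1, radius_range_mm[1], radius_range_mm[2])
      amp <- runif(1, 0.7, 1.3)
      d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
        (xyz[, 3] - ctr[3])^2
      v <- v + amp * exp(-d2 / (2 * r^2))
      if (mirrored) {
        d2m <- (xyz[, 1] - (2 * mid_x - ctr[1]))^2 + (xyz[, 2] - ctr[2])^2 +
          (xyz[, 3] - ctr[3])^2
        v <- v + amp * exp(-d2m / (2 * r^2))
      }
    }
    v <- v - mean(v)
    s <- sqrt(mean(v^2))
    if (s < 1e-12) return(NULL)
    v / s
  }

  with_seed(seed, {
    S <- matrix(0, K, grid$n_voxels)
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        v <- one_source()
        if (is.null(v)) next
        if (excess_kurtosis(v) < min_kurtosis) next
        if (k == 1L ||
            all(abs(S[seq_len(k - 1), , drop = FALSE] %*% v) / grid$n_voxels
                < max_cor)) {
          S[k, ] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place source ", k, " with pairwise |correlation| < ",
             max_cor, " and excess kurtosis >= ", min_kurtosis, " in ",
             max_tries, " attempts")
      }
    }
    S
  })
}

#' Specify an age-dependent loading function for one component
#'
#' Loadings play the role of per-subject ICA weights: subject i expresses
#' component k with weight `intercept + age*age_i (+ age2*age_i^2)` plus
#' independent Gaussian noise.
#'
#' @param order polynomial order of the age trend, 1 or 2.
#' @param intercept,age,age2 coefficients in raw-age basis (weight units per
#'   year^k); `age2` must be 0 when `order == 1`.
#' @param noise_sd standard deviation of the loading noise (>= 0).
#' @return An object of class `loading_spec`.
#' @export
loading_spec <- function(order, intercept, age, age2 = 0, noise_sd = 0.02) {
  stopifnot(order %in% c(1L, 2L), noise_sd >= 0)
  if (order == 1L && age2 != 0) stop("order-1 loading cannot have an age2 term")
  structure(
    list(order = as.integer(order), intercept = intercept, age = age,
         age2 = age2, noise_sd = noise_sd),
    class = "loading_spec"
  )
}

# Deterministic part of a loading function evaluated at given ages.
loading_mean <- function(spec, ages) {
  spec$intercept + spec$age * ages + spec$age2 * ages^2
}

#' Default loading specifications (three linear declines + one inverted U)
#'
#' Mirrors the qualitative structure of adult-lifespan gray-matter networks:
#' most network weights decline linearly with age while one (temporal-lobe
#' like) component rises to a vertex near age 50 and then falls. Loading
#' noise sd 0.1 puts the deterministic-trend-to-noise ratio between ~3 and
#' ~4.7 across components; the per-component loading noise is also what
#' makes the mixing columns linearly independent (the centred linear trends
#' are mutually proportional), so it is deliberately large relative to the
#' voxelwise noise.
#'
#' @return A list of four [loading_spec()] objects.
#' @export
default_loading_specs <- function() {
  list(
    loading_spec(1L, intercept = 4.0, age = -0.040, noise_sd = 0.2),
    loading_spec(1L, intercept = 4.4, age = -0.045, noise_sd = 0.2),
    loading_spec(1L, intercept = 4.8, age = -0.050, noise_sd = 0.2),
    # vertex form 1.0 - 4e-4 (age - 50)^2 expanded in the raw-age basis
    loading_spec(2L, intercept = 0.0, age = 0.04, age2 = -4e-4,
                 noise_sd = 0.033)
  )
}

#' Assemble the ground truth for a synthetic cohort
#'
#' @param grid a [volume_grid()].
#' @param K number of latent sources (>= 2).
#' @param loading_specs list of `K` [loading_spec()] objects.
#' @param site_effect_sd in-mask sd of each per-site additive voxel map.
#' @param sex_effect_sd in-mask sd of the additive sex-offset voxel map.
#' @param residual_noise_sd sd of i.i.d. voxelwise Gaussian noise.
#' @param baseline positive offset keeping voxel values gray-matter-like.
#' @param seed integer seed; fully determines sources and confound maps, and
#'   (via [derive_seed()]) the noise drawn by [synthesize()].
#' @param ... further arguments to [make_sources()].
#' @return An object of class `sbm_ground_truth`.
#' @export
ground_truth <- function(grid = default_grid(), K = 4L,
                         loading_specs = default_loading_specs(),
                         site_effect_sd = 0.05, sex_effect_sd = 0.05,
                         residual_noise_sd = 0.008, baseline = 5,
                         seed = 1L, ...) {
  stopifnot(K >= 2, length(loading_specs) == K)
  sources <- make_sources(grid, K, seed = derive_seed(seed, "sources"), ...)
  conf <- with_seed(derive_seed(seed, "confounds"), {
    smooth_map <- function(sd_target) {
      if (sd_target == 0) return(numeric(grid$n_voxels))
      vol <- array(rnorm(prod(grid$shape)), dim = grid$shape)
      vol <- smooth_volume(vol, grid, fwhm_mm = 9)
      v <- mask_values(grid, vol)
      v <- v - mean(v)
      v * sd_target / sqrt(mean(v^2))
    }
    list(
      site = t(vapply(1:3, function(s) smooth_map(site_effect_sd),
                      numeric(grid$n_voxels))),
      sex = smooth_map(sex_effect_sd)
    )
  })
  structure(
    list(grid = grid, K = as.integer(K), sources = sources,
         loading_specs = loading_specs, site_effects = conf$site,
         sex_effect = conf$sex, residual_noise_sd = residual_noise_sd,
         baseline = baseline, seed = as.integer(seed)),
    class = "sbm_ground_truth"
  )
}

#' Synthesize a subject-by-voxel gray-matter matrix from ground truth
#'
#' Subject i's in-mask voxel vector is
#' `sum_k w_ik * s_k + site_effect(site_i) + sex_i * sex_effect + eps + baseline`
#' with `w_ik` the loading function of component k evaluated at `age_i` plus
#' Gaussian loading noise, and `eps` i.i.d. voxelwise Gaussian noise.
#'
#' @param gt an [ground_truth()] object.
#' @param cohort an [sample_cohort()] covariate table.
#' @param seed integer seed for loading and voxel noise (default derived from
#'   `gt$seed` so a ground truth fully determines its data).
#' @return An object of class `sbm_data_matrix` with fields `values`
#'   (n x n_voxels), `grid`, `cohort`, and `loadings` (the realized n x K
#'   loading matrix, kept for recovery diagnostics).
#' @export
synthesize <- function(gt, cohort, seed = derive_seed(gt$seed, "synthesize")) {
  stopifnot(inherits(gt, "sbm_ground_truth"))
  n <- nrow(cohort)
  if (n < 10) stop("cohorts must have at least 10 subjects")
  grid <- gt$grid
  with_seed(seed, {
    W <- vapply(seq_len(gt$K), function(k) {
      spec <- gt$loading_specs[[k]]
      loading_mean(spec, cohort$age) +
        if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    }, numeric(n))
    X <- W %*% gt$sources
    site_i <- as.integer(cohort$site)
    X <- X + gt$site_effects[site_i, , drop = FALSE]
    sex_num <- as.numeric(cohort$sex == levels(cohort$sex)[2])
    X <- X + outer(sex_num, gt$sex_effect)
    if (gt$residual_noise_sd > 0) {
      X <- X + matrix(rnorm(length(X), 0, gt$residual_noise_sd), nrow = n)
    }
    X <- X + gt$baseline
    data_matrix(X, grid, cohort, loadings = W)
  })
}

#' Construct a subject-by-voxel data matrix
#'
#' @param values n_subjects x n_voxels numeric matrix over in-mask voxels.
#' @param grid the [volume_grid()] the columns refer to.
#' @param cohort covariate table aligned with the rows.
#' @param loadings optional realized loading matrix (synthetic mode only).
#' @return An object of class `sbm_data_matrix`.
#' @export
data_matrix <- function(values, grid, cohort, loadings = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != grid$n_voxels) {
    stop("data matrix has ", ncol(values), " columns but the grid mask has ",
         grid$n_voxels, " voxels")
  }
  if (nrow(values) != nrow(cohort)) {
    stop("data matrix rows (", nrow(values), ") must match cohort size (",
         nrow(cohort), ")")
  }
  if (!all(is.finite(values))) stop("data matrix contains non-finite entries")
  structure(list(values = values, grid = grid, cohort = cohort,
                 loadings = loadings),
            class = "sbm_data_matrix")
}

#' @export
print.sbm_data_matrix <- function(x, ...) {
  cat(sprintf("sbm_data_matrix: %d subjects x %d in-mask voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
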