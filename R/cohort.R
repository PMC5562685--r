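#' Default age-bin table for an adult-lifespan cohort
#'
#' Decade bins spanning ages 20-86 with subject counts mirroring a published
#' three-site adult-lifespan structural MRI sample (total n = 536, heaviest
#' sampling in the seventh decade, very few subjects over 80).
#'
#' @return A data.frame with columns `lower`, `upper`, `count`.
#' @export
default_age_bins <- function() {
  data.frame(
    lower = c(20, 30, 40, 50, 60, 70, 80),
    upper = c(29, 39, 49, 59, 69, 79, 86),
    count = c(93, 106, 86, 88, 116, 41, 6)
  )
}

#' Sample a synthetic cohort's covariate table
#'
#' Ages are uniform within each bin; sex and scanner site are sampled
#' independently with the given probabilities. Defaults reproduce the
#' marginal structure of a 536-subject, three-site, age 20-86 cohort
#' (273/536 female; site frequencies 289/179/68).
#'
#' @param n number of subjects; must equal `sum(age_bins$count)`.
#' @param age_bins data.frame with `lower`, `upper`, `count` columns.
#' @param sex_ratio probability a subject is female.
#' @param site_probs length-3 probabilities for sites 1-3 (normalised
#'   internally).
#' @param seed integer seed; the same seed gives a bit-identical cohort.
#' @return A data.frame of class `sbm_cohort` with columns `id`, `age`,
#'   `sex` (factor `F`/`M`) and `site` (factor `site1`-`site3`).
#' @examples
#' coh <- sample_cohort(seed = 1)
#' nrow(coh)  # 536
#' @export
sample_cohort <- function(n = sum(age_bins$count),
                          age_bins = default_age_bins(),
                          sex_ratio = 273 / 536,
                          site_probs = c(289, 179, 68) / 536,
                          seed = NULL) {
  stopifnot(all(c("lower", "upper", "count") %in% names(age_bins)))
  if (sum(age_bins$count) != n) {
    stop("age bin counts must sum to n (got ", sum(age_bins$count),
         " for n = ", n, ")")
  }
  stopifnot(length(site_probs) == 3L, all(site_probs >= 0),
            sex_ratio >= 0, sex_ratio <= 1)
  if (n < 10) stop("cohorts must have at least 10 subjects")
  with_seed(seed, {
    ages <- unlist(lapply(seq_len(nrow(age_bins)), function(b) {
      runif(age_bins$count[b], age_bins$lower[b], age_bins$upper[b])
    }))
    sex <- factor(ifelse(runif(n) < sex_ratio, "F", "M"), levels = c("F", "M"))
    site <- factor(
      sample(paste0("site", 1:3), n, replace = TRUE,
             prob = site_probs / sum(site_probs)),
      levels = paste0("site", 1:3)
    )
    coh <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = ages, sex = sex, site = site,
      stringsAsFactors = FALSE
    )
    class(coh) <- c("sbm_cohort", "data.frame")
    coh
  })
}

#' Read a cohort covariate table from TSV
#'
#' Expects columns `id`, `age`, `sex`, `site`.
#' @param path TSV file path.
#' @return An `sbm_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  coh <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "site")
  if (!all(need %in% names(coh))) {
    stop("covariate table must have columns: ", paste(need, collapse = ", "))
  }
  coh$sex <- factor(coh$sex)
  coh$site <- factor(coh$site)
  class(coh) <- c("sbm_cohort", "data.frame")
  coh
}

#' Write a cohort covariate table to TSV
#' @param cohort an `sbm_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
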