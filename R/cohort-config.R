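#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic data-generating process that the
#' estimators in this package are designed to recover. The defaults emulate
#' the study conditions of a biennial ageing-cohort panel (four survey waves
#' 2011--2018) observed across ~125 prefecture-level regions, eight of which
#' adopt a regional carbon-trading policy in a staggered calendar (five
#' pilots from 2013, two joining in 2014, one in 2016). Outcomes are binary
#' events coded on the per-1,000 scale (0 or 1,000), so all effects read as
#' events per 1,000 persons.
#'
#' Covariate effects are applied to *centred* covariates, so `baseline_rate`
#' is the marginal incidence per 1,000 in the absence of treatment, and the
#' treated-post incidence is lower by approximately
#' `treatment_effect`/1,000. The moderation term multiplies the treatment
#' indicator by the centred moderator, which leaves the plain
#' difference-in-differences estimand equal to `treatment_effect` while the
#' triple-interaction coefficient of the moderation model equals
#' `moderation_effect`.
#'
#' @param n_regions Number of regions in the sampling frame.
#' @param treated_cohorts Data frame with columns `adoption_year` and
#'   `n_regions`, one row per adoption cohort. The default reproduces the
#'   pilot calendar 2013 (5 regions), 2014 (2), 2016 (1).
#' @param waves Integer vector of survey calendar years, strictly increasing.
#' @param n_individuals_per_region Individuals sampled per region; each is
#'   observed at every wave.
#' @param baseline_rate Marginal event rate per 1,000 under no treatment.
#' @param covariate_effects Named numeric vector of per-1,000 outcome shifts
#'   per unit of (centred) covariate. Defaults are the published pan-cancer
#'   linear-probability coefficients for the full covariate set.
#' @param treatment_effect Post-adoption outcome shift per 1,000 (tau).
#' @param moderation_effect Additional per-1,000 shift per unit of the
#'   (centred) depression-score moderator among treated-post observations.
#' @param pretrend_slope Per-1,000 per-wave differential trend in ever-treated
#'   regions; 0 means parallel trends hold.
#' @param region_sd Standard deviation (per 1,000) of the Gaussian
#'   region-level random effect creating within-region clustering.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_regions = 20, n_individuals_per_region = 10)
#' cfg$treated_cohorts
#' @export
cohort_config <- function(n_regions = 125,
                          treated_cohorts = data.frame(
                            adoption_year = c(2013L, 2014L, 2016L),
                            n_regions = c(5L, 2L, 1L)
                          ),
                          waves = c(2011L, 2013L, 2015L, 2018L),
                          n_individuals_per_region = 200,
                          baseline_rate = 117.916,
                          covariate_effects = c(
                            gender = -26.252, age = -0.592, bmi = 0.187,
                            education = 4.091, rural = -8.297,
                            sleep = -4.579, smoke = -17.569,
                            drink = -9.519, hypertension = -1.515,
                            diabetes = -1.048, cesd = 3.045
                          ),
                          treatment_effect = -47.200,
                          moderation_effect = -3.248,
                          pretrend_slope = 0,
                          region_sd = 10,
                          seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    treated_cohorts = as.data.frame(treated_cohorts),
    waves = as.integer(waves),
    n_individuals_per_region = as.integer(n_individuals_per_region),
    baseline_rate = baseline_rate,
    covariate_effects = covariate_effects,
    treatment_effect = treatment_effect,
    moderation_effect = moderation_effect,
    pretrend_slope = pretrend_slope,
    region_sd = region_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num <- c(cfg$baseline_rate, cfg$covariate_effects, cfg$treatment_effect,
           cfg$moderation_effect, cfg$pretrend_slope, cfg$region_sd)
  if (!all(is.finite(num))) {
    stop("cohort_config: all rate and effect parameters must be finite",
         call. = FALSE)
  }
  if (cfg$n_regions < 1L || cfg$n_individuals_per_region < 1L) {
    stop("cohort_config: n_regions and n_individuals_per_region must be >= 1",
         call. = FALSE)
  }
  if (length(cfg$waves) < 1L || is.unsorted(cfg$waves, strictly = TRUE)) {
    stop("cohort_config: waves must be strictly increasing", call. = FALSE)
  }
  tc <- cfg$treated_cohorts
  if (nrow(tc) > 0L) {
    if (!all(c("adoption_year", "n_regions") %in% names(tc))) {
      stop("treated_cohorts needs columns adoption_year and n_regions",
           call. = FALSE)
    }
    if (sum(tc$n_regions) > cfg$n_regions) {
      stop("cohort_config: sum of cohort region counts exceeds n_regions",
           call. = FALSE)
    }
    if (any(tc$adoption_year < min(cfg$waves) |
            tc$adoption_year > max(cfg$waves))) {
      stop("cohort_config: cohort adoption years outside the wave span",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  regions: %d (%d treated across %d cohorts)\n",
              x$n_regions, sum(x$treated_cohorts$n_regions),
              nrow(x$treated_cohorts)))
  cat(sprintf("  waves: %s\n", paste(x$waves, collapse = ", ")))
  cat(sprintf("  individuals/region: %d\n", x$n_individuals_per_region))
  cat(sprintf("  baseline %.3f per 1,000; tau %.3f; moderation %.3f; pre-trend %.3f\n",
              x$baseline_rate, x$treatment_effect, x$moderation_effect,
              x$pretrend_slope))
  invisible(x)
}
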