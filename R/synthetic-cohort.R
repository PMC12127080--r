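# Synthetic cohort generator: policy schedules, individual-by-wave panels and
# region-year pollution indicator tables with the statistical structure the
# estimators assume, so every estimator is testable by parameter recovery.

#' Generate a staggered policy adoption schedule
#'
#' Randomly assigns regions to the adoption cohorts of `config`, leaving the
#' remainder never-treated. Assignment is a deterministic function of
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `policy_schedule`: a data frame with columns `region_id` and
#'   `adoption_year` (`NA` for never-treated regions), one row per region.
#' @examples
#' sch <- generate_policy_schedule(cohort_config(n_regions = 20))
#' table(sch$adoption_year, useNA = "ifany")
#' @export
generate_policy_schedule <- function(config) {
  validate_cohort_config(config)
  regions <- sprintf("R%03d", seq_len(config$n_regions))
  adoption <- rep(NA_integer_, config$n_regions)
  tc <- config$treated_cohorts
  if (nrow(tc) > 0L) {
    picked <- withr::with_seed(config$seed,
      sample(config$n_regions, sum(tc$n_regions)))
    at <- 0L
    for (k in seq_len(nrow(tc))) {
      idx <- picked[(at + 1L):(at + tc$n_regions[k])]
      adoption[idx] <- as.integer(tc$adoption_year[k])
      at <- at + tc$n_regions[k]
    }
  }
  schedule <- data.frame(region_id = regions, adoption_year = adoption,
                         stringsAsFactors = FALSE)
  class(schedule) <- c("policy_schedule", "data.frame")
  schedule
}

# distribution means used to centre covariates; kept next to the draws below
.covariate_draws <- function(n) {
  list(
    gender       = stats::rbinom(n, 1L, 0.5),
    age          = stats::runif(n, 45, 85),
    bmi          = stats::rnorm(n, 23.5, 3.5),
    education    = stats::rbinom(n, 1L, 0.2),
    rural        = stats::rbinom(n, 1L, 0.6),
    sleep        = stats::rnorm(n, 6.5, 1.5),
    smoke        = stats::rbinom(n, 1L, 0.3),
    drink        = stats::rbinom(n, 1L, 0.33),
    hypertension = stats::rbinom(n, 1L, 0.25),
    diabetes     = stats::rbinom(n, 1L, 0.1)
  )
}

#' Generate a synthetic individual-by-wave panel
#'
#' Draws one record per individual per wave. Time-invariant covariates
#' (gender, baseline age, BMI, education, rural residence, smoking, drinking,
#' hypertension, diabetes) are drawn once per individual; sleep duration and
#' the depression score (`cesd`, non-negative) are drawn per record. The
#' binary event outcome `cancer` is Bernoulli with probability
#' `clamp(linear index / 1000, 0, 1)` and stored on the per-1,000 scale
#' (0 or 1,000). The linear index is
#' `baseline + sum(effects * centred covariates) + tau * treat_post +
#' moderation * treat_post * centred(cesd) + pretrend * treat * centred wave
#' + region effect`.
#'
#' The fraction of records whose implied probability needed clamping is
#' recorded in attribute `clamp_fraction`; a warning is raised above 1%.
#'
#' @param config A [cohort_config()].
#' @param schedule A schedule from [generate_policy_schedule()].
#' @return A data frame with identifiers (`individual_id`, `region_id`,
#'   `wave`), the covariates, `cesd`, and the outcome `cancer`.
#' @examples
#' cfg <- cohort_config(n_regions = 10, n_individuals_per_region = 5)
#' pan <- generate_panel(cfg, generate_policy_schedule(cfg))
#' head(pan)
#' @export
generate_panel <- function(config, schedule) {
  validate_cohort_config(config)
  stopifnot(inherits(schedule, "data.frame"),
            all(c("region_id", "adoption_year") %in% names(schedule)))

  n_waves <- length(config$waves)
  n_ind <- config$n_regions * config$n_individuals_per_region

  withr::with_seed(config$seed, {
    region_id <- rep(schedule$region_id, each = config$n_individuals_per_region)
    individual_id <- sprintf("%s-I%04d", region_id,
                             rep(seq_len(config$n_individuals_per_region),
                                 times = config$n_regions))
    cov1 <- .covariate_draws(n_ind)
    region_effect <- stats::rnorm(config$n_regions, 0, config$region_sd)
    names(region_effect) <- schedule$region_id

    # expand to the long panel
    rep_w <- function(x) rep(x, times = n_waves)
    panel <- data.frame(
      individual_id = rep_w(individual_id),
      region_id = rep_w(region_id),
      wave = rep(config$waves, each = n_ind),
      stringsAsFactors = FALSE
    )
    wave_offset <- panel$wave - config$waves[1L]
    panel$gender <- rep_w(cov1$gender)
    panel$age <- rep_w(cov1$age) + wave_offset
    panel$bmi <- rep_w(cov1$bmi)
    panel$education <- rep_w(cov1$education)
    panel$rural <- rep_w(cov1$rural)
    panel$sleep <- pmax(stats::rnorm(nrow(panel), rep_w(cov1$sleep), 0.5), 1)
    panel$smoke <- rep_w(cov1$smoke)
    panel$drink <- rep_w(cov1$drink)
    panel$hypertension <- rep_w(cov1$hypertension)
    panel$diabetes <- rep_w(cov1$diabetes)
    panel$cesd <- stats::rgamma(nrow(panel), shape = 2, scale = 4)

    adoption <- schedule$adoption_year[match(panel$region_id,
                                             schedule$region_id)]
    treat <- as.integer(!is.na(adoption))
    treat_post <- as.integer(treat == 1L & panel$wave >= adoption)

    idx <- rep(config$baseline_rate, nrow(panel))
    for (nm in names(config$covariate_effects)) {
      x <- panel[[nm]]
      if (is.null(x)) next
      idx <- idx + config$covariate_effects[[nm]] * (x - mean(x))
    }
    idx <- idx + config$treatment_effect * treat_post
    idx <- idx + config$moderation_effect * treat_post *
      (panel$cesd - mean(panel$cesd))
    wave_idx <- match(panel$wave, config$waves)
    idx <- idx + config$pretrend_slope * treat * (wave_idx - mean(seq_len(n_waves)))
    idx <- idx + region_effect[panel$region_id]

    prob <- idx / 1000
    clamped <- prob < 0 | prob > 1
    prob <- pmin(pmax(prob, 0), 1)
    panel$cancer <- 1000 * stats::rbinom(nrow(panel), 1L, prob)
  })

  clamp_fraction <- mean(clamped)
  if (clamp_fraction > 0.01) {
    warning(sprintf(
      "linear index clamped to [0, 1] for %.1f%% of records; effects near the boundary are attenuated",
      100 * clamp_fraction))
  }
  attr(panel, "clamp_fraction") <- clamp_fraction
  panel <- panel[order(panel$individual_id, panel$wave), ]
  rownames(panel) <- NULL
  panel
}

#' Add extra synthetic event outcomes to a panel
#'
#' Draws additional binary per-1,000 event columns (for example one column
#' per cancer site) sharing the panel's treatment structure but with their
#' own baseline rates and treatment effects. Used to exercise the
#' per-outcome regression loop and the pan-cancer index construction.
#'
#' @param panel A panel data frame.
#' @param schedule The policy schedule the panel was generated under.
#' @param outcomes Data frame with columns `name`, `baseline` (per 1,000) and
#'   `tau` (per-1,000 treatment effect), one row per outcome.
#' @param seed Integer seed for the outcome draws.
#' @return The panel with one new 0/1,000 column per requested outcome.
#' @export
add_event_outcomes <- function(panel, schedule, outcomes, seed = 1L) {
  stopifnot(all(c("name", "baseline", "tau") %in% names(outcomes)),
            nrow(outcomes) >= 1L)
  adoption <- schedule$adoption_year[match(panel$region_id, schedule$region_id)]
  treat_post <- as.integer(!is.na(adoption) & panel$wave >= adoption)
  withr::with_seed(seed, {
    for (k in seq_len(nrow(outcomes))) {
      p <- (outcomes$baseline[k] + outcomes$tau[k] * treat_post) / 1000
      p <- pmin(pmax(p, 0), 1)
      panel[[outcomes$name[k]]] <- 1000 * stats::rbinom(nrow(panel), 1L, p)
    }
  })
  panel
}

#' Generate region-by-year pollution indicator tables
#'
#' Produces one row per region per year with four strictly positive
#' indicator columns (industrial SO2, industrial dust, industrial wastewater,
#' annual-mean PM2.5). Columns are correlated through a shared log-normal
#' region factor whose loading is `shared_loading`; a loading of 0 gives
#' independent indicators.
#'
#' @param schedule A policy schedule (its `region_id` column defines the
#'   regions).
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @param shared_loading Loading of the shared region factor on the log scale.
#' @return A data frame `region_id, year, so2, dust, wastewater, pm25`.
#' @export
generate_pollution_indicators <- function(schedule,
                                          years = c(2011L, 2013L, 2015L, 2018L),
                                          seed = 1L,
                                          shared_loading = 0.6) {
  regions <- unique(schedule$region_id)
  grid <- expand.grid(region_id = regions, year = as.integer(years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$region_id, grid$year), ]
  rownames(grid) <- NULL
  base <- c(so2 = 40000, dust = 15000, wastewater = 3000, pm25 = 55)
  sds <- c(so2 = 0.5, dust = 0.5, wastewater = 0.4, pm25 = 0.25)
  withr::with_seed(seed, {
    z <- stats::rnorm(length(regions))
    names(z) <- regions
    for (nm in names(base)) {
      eps <- stats::rnorm(nrow(grid), 0, sds[[nm]])
      grid[[nm]] <- base[[nm]] *
        exp(shared_loading * z[grid$region_id] + eps)
    }
  })
  grid
}

#' Write and read panel-like tables
#'
#' Tables are written as plain CSV or, when the `arrow` package is available,
#' as the Feather columnar binary format; the format is inferred from the
#' file extension (`.csv` vs `.feather`).
#'
#' @param x A data frame (panel, schedule, or indicator table).
#' @param path Output path ending in `.csv` or `.feather`.
#' @return `write_panel_table` returns `path` invisibly; `read_panel_table`
#'   returns a data frame.
#' @export
write_panel_table <- function(x, path) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for feather output", call. = FALSE)
    }
    arrow::write_feather(x, path)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_panel_table
#' @export
read_panel_table <- function(path) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for feather input", call. = FALSE)
    }
    as.data.frame(arrow::read_feather(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
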