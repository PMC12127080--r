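# Orchestrates the full analysis in the order the study design sequences
# it: simulate -> per-outcome DID -> pan-cancer DID -> parallel trends ->
# placebo -> balancing robustness -> moderation -> subgroups, emitting CSV
# tables, figures and a manifest.

MODEL1_COVARIATES <- c("gender", "age", "bmi")
MODEL2_COVARIATES <- c("gender", "age", "bmi", "education", "rural",
                       "sleep", "smoke", "drink", "hypertension", "diabetes")

#' Default run configuration for the full analysis
#'
#' @param seed Master seed; every stage seed derives from it.
#' @param cohort A [cohort_config()] for the simulated inputs (its seed is
#'   overridden by `seed`).
#' @param placebo_B Number of placebo permutations.
#' @param n_extra_outcomes Number of additional per-site event outcomes to
#'   simulate for the per-outcome screen (six of which carry a true effect).
#' @return A named list understood by [run_full_analysis()].
#' @export
default_run_config <- function(seed = 1L,
                               cohort = cohort_config(seed = seed),
                               placebo_B = 500L,
                               n_extra_outcomes = 12L) {
  list(seed = as.integer(seed), cohort = cohort,
       placebo_B = as.integer(placebo_B),
       n_extra_outcomes = as.integer(n_extra_outcomes),
       model1_covariates = MODEL1_COVARIATES,
       model2_covariates = MODEL2_COVARIATES)
}

#' Read a run configuration from a YAML file
#'
#' The file may set `seed`, `placebo_B`, `n_extra_outcomes`, covariate
#' lists, and any [cohort_config()] field under a `cohort:` block.
#'
#' @param path YAML file path.
#' @return A run-configuration list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$treated_cohorts)) {
    cohort_args$treated_cohorts <-
      do.call(rbind, lapply(cohort_args$treated_cohorts, as.data.frame))
  }
  if (!is.null(cohort_args$covariate_effects)) {
    cohort_args$covariate_effects <- unlist(cohort_args$covariate_effects)
  }
  cohort_args$seed <- seed
  cfg <- default_run_config(
    seed = seed,
    cohort = do.call(cohort_config, cohort_args),
    placebo_B = if (!is.null(raw$placebo_B)) as.integer(raw$placebo_B) else 500L,
    n_extra_outcomes = if (!is.null(raw$n_extra_outcomes))
      as.integer(raw$n_extra_outcomes) else 12L)
  if (!is.null(raw$model1_covariates)) {
    cfg$model1_covariates <- unlist(raw$model1_covariates)
  }
  if (!is.null(raw$model2_covariates)) {
    cfg$model2_covariates <- unlist(raw$model2_covariates)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.save_plot <- function(p, path, width = 6, height = 4) {
  tryCatch({
    grDevices::png(path, width = width * 96, height = height * 96, res = 96)
    print(p)
    grDevices::dev.off()
    path
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    NA_character_
  })
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes every stage of the quasi-experimental analysis in sequence and
#' writes its artifacts to `output_dir`: the per-outcome forest table and
#' plot, the pan-cancer main table (reduced and full covariate models), the
#' event-study curve and plot, the placebo distribution and plot, balancing
#' diagnostics with entropy-balanced and matched re-estimates, the two
#' moderation tables (pollution index, depression score), the subgroup
#' table with Chow tests, and a JSON manifest of seeds and settings. A
#' stage failure aborts with the stage name; artifacts of completed stages
#' are preserved.
#'
#' @param config A run configuration from [default_run_config()] or
#'   [read_run_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_full_analysis <- function(config = default_run_config(),
                              output_dir = "staggerdid-output",
                              verbose = TRUE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  results <- list()
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- config$cohort
  cohort$seed <- config$seed

  schedule <- stage("simulate", {
    s <- generate_policy_schedule(cohort)
    write_panel_table(s, file.path(output_dir, "policy_schedule.csv"))
    s
  })
  panel <- stage("simulate", {
    p <- generate_panel(cohort, schedule)
    # extra per-site outcomes: six carrying a true effect, the rest null
    k <- config$n_extra_outcomes
    if (k > 0) {
      sites <- sprintf("site_%02d", seq_len(k))
      taus <- c(rep(-8, min(6, k)), rep(0, max(0, k - 6)))
      p <- add_event_outcomes(
        p, schedule,
        data.frame(name = sites, baseline = 12, tau = taus),
        seed = config$seed + 1L)
    }
    p
  })

  screen <- stage("per-outcome DID", {
    sites <- grep("^site_", names(panel), value = TRUE)
    sc <- estimate_per_outcome(panel, schedule, outcomes = sites,
                               covariates = config$model1_covariates)
    utils::write.csv(sc$table,
                     file.path(output_dir, "per_outcome_forest.csv"),
                     row.names = FALSE)
    .save_plot(autoplot.outcome_screen(sc),
               file.path(output_dir, "per_outcome_forest.png"))
    sc
  })

  main <- stage("pan-cancer DID", {
    sig <- screen$table$outcome[screen$table$p_value < 0.05 &
                                  screen$table$estimate < 0]
    pc_panel <- if (length(sig) >= 1) {
      build_pan_cancer_outcome(panel, sig, name = "pan_site")
    } else panel
    m1 <- estimate_did(panel, schedule,
                       covariates = config$model1_covariates)
    m2 <- estimate_did(panel, schedule,
                       covariates = config$model2_covariates)
    tab <- merge(fit_table(m1), fit_table(m2), by = "term", all = TRUE,
                 suffixes = c("_model1", "_model2"), sort = FALSE)
    utils::write.csv(tab, file.path(output_dir, "main_table.csv"),
                     row.names = FALSE)
    write_fit_json(m2, file.path(output_dir, "main_model2.json"))
    list(model1 = m1, model2 = m2, pan_members = sig)
  })

  es <- stage("parallel trends", {
    e <- estimate_event_study(panel, schedule,
                              covariates = config$model1_covariates)
    utils::write.csv(e$curve, file.path(output_dir, "event_study.csv"),
                     row.names = FALSE)
    .save_plot(autoplot.event_study(e),
               file.path(output_dir, "event_study.png"))
    e
  })

  placebo <- stage("placebo", {
    pl <- placebo_distribution(panel, schedule,
                               covariates = config$model1_covariates,
                               B = config$placebo_B,
                               seed = config$seed + 2L)
    utils::write.csv(data.frame(draw = pl$draws),
                     file.path(output_dir, "placebo_draws.csv"),
                     row.names = FALSE)
    .save_plot(autoplot.permutation_distribution(pl),
               file.path(output_dir, "placebo.png"))
    pl
  })

  balanced <- stage("balancing robustness", {
    pan <- build_treatment_indicator(panel, schedule)
    covs <- config$model2_covariates
    tr <- pan$treat == 1
    w <- entropy_balance(pan[tr, covs], pan[!tr, covs])
    bt <- balance_table(pan, w, covariates = covs)
    utils::write.csv(bt, file.path(output_dir, "balance_table.csv"),
                     row.names = FALSE)
    pan$.w <- 1
    pan$.w[!tr] <- w$weights
    refit <- estimate_did(pan, schedule, covariates = covs,
                          weights = ".w")
    utils::write.csv(fit_table(refit),
                     file.path(output_dir, "balanced_reestimate.csv"),
                     row.names = FALSE)
    list(weights = w, table = bt, refit = refit)
  })

  moderation <- stage("moderation", {
    ind <- generate_pollution_indicators(schedule, years = cohort$waves,
                                         seed = config$seed + 3L)
    idx <- build_pollution_index(ind)
    pan <- merge_pollution_index(panel, idx)
    m_ext <- estimate_moderation(pan, schedule, moderator = "pollution_index",
                                 covariates = config$model2_covariates)
    m_int <- estimate_moderation(panel, schedule, moderator = "cesd",
                                 covariates = config$model2_covariates)
    utils::write.csv(rbind(cbind(moderator = "pollution_index",
                                 fit_table(m_ext)),
                           cbind(moderator = "cesd", fit_table(m_int))),
                     file.path(output_dir, "moderation_table.csv"),
                     row.names = FALSE)
    list(external = m_ext, internal = m_int, index = idx)
  })

  subgroups <- stage("subgroups", {
    sg <- list(
      gender = subgroup_analysis(panel, schedule, "gender",
                                 covariates = config$model2_covariates),
      bmi = subgroup_analysis(panel, schedule, "bmi",
                              cutpoints = c(18.5, 25),
                              covariates = config$model2_covariates),
      smoke = subgroup_analysis(panel, schedule, "smoke",
                                covariates = config$model2_covariates)
    )
    tab <- do.call(rbind, lapply(names(sg), function(nm) {
      cbind(variable = nm, sg[[nm]]$table,
            chow_F = sg[[nm]]$chow_statistic,
            chow_p = sg[[nm]]$chow_p_value)
    }))
    utils::write.csv(tab, file.path(output_dir, "subgroup_table.csv"),
                     row.names = FALSE)
    sg
  })

  manifest <- list(
    package = "staggerdid",
    package_version = as.character(utils::packageVersion("staggerdid")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    placebo_B = config$placebo_B,
    waves = cohort$waves,
    n_regions = cohort$n_regions,
    n_individuals_per_region = cohort$n_individuals_per_region,
    treatment_effect = cohort$treatment_effect,
    model1_covariates = config$model1_covariates,
    model2_covariates = config$model2_covariates,
    artifacts = list.files(output_dir)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(schedule = schedule, panel = panel, screen = screen,
                 main = main, event_study = es, placebo = placebo,
                 balanced = balanced, moderation = moderation,
                 subgroups = subgroups, manifest = manifest))
}
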