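# The three regression designs of the analysis: staggered DID, relative-time
# event study, and triple-interaction moderation, plus the per-outcome loop,
# pan-cancer index construction, and subgroup/Chow machinery.

#' Staggered difference-in-differences estimate
#'
#' Fits the linear probability model
#' `outcome = a0 + tau * treat_post + lambda * X + time FE + e` with
#' cluster-robust standard errors. The coefficient on `treat_post` estimates
#' the average post-adoption outcome shift per 1,000. An ever-treated main
#' effect (`treat`) is included by default so that, in the two-period
#' simultaneous-adoption case, the estimator reduces exactly to the
#' four-cell difference of group-by-period means; set
#' `include_treat_main = FALSE` to fit the bare interaction specification.
#'
#' @param panel Panel data frame.
#' @param schedule Policy schedule.
#' @param covariates Control-variable columns.
#' @param outcome Outcome column (per-1,000 event coding).
#' @param fixed_effects Fixed-effect factors (default time/wave).
#' @param cluster Cluster column for the sandwich covariance.
#' @param weights Optional observation-weight column.
#' @param conf_level Confidence level.
#' @param include_treat_main Include the ever-treated group main effect.
#' @return A `did_fit`; the treatment term is named `treat_post`.
#' @export
estimate_did <- function(panel, schedule,
                         covariates = character(),
                         outcome = "cancer",
                         fixed_effects = "wave",
                         cluster = "region_id",
                         weights = NULL,
                         conf_level = 0.95,
                         include_treat_main = TRUE) {
  panel <- build_treatment_indicator(panel, schedule)
  if (sum(panel$treat_post) == 0L) {
    stop("no treated post-adoption observations; DID is not identified",
         call. = FALSE)
  }
  # the ever-treated main effect is collinear with region fixed effects, and
  # with the intercept when every region in the panel is a pilot
  use_treat_main <- include_treat_main &&
    !"region_id" %in% fixed_effects &&
    stats::var(panel$treat) > 0
  terms <- if (use_treat_main) c("treat", "treat_post") else "treat_post"
  spec <- model_spec(outcome, terms = terms, covariates = covariates,
                     fixed_effects = fixed_effects, cluster = cluster,
                     weights = weights, conf_level = conf_level)
  fit <- fit_linear(panel, spec)
  attr(fit, "treatment_term") <- "treat_post"
  fit
}

#' Relative-time event study for the parallel-trends assumption
#'
#' Replaces the single interaction with dummies for relative time to
#' adoption measured in survey waves, `rel = wave index - adoption wave
#' index`, binned at the window ends, with never-treated units contributing
#' to the baseline. The reference period (default -1, the wave before
#' adoption) is omitted and reported as an identically-zero coefficient with
#' a zero-width interval.
#'
#' @inheritParams estimate_did
#' @param pre_periods Number of pre-adoption relative periods (window
#'   extends to `-pre_periods`, earlier periods binned into it).
#' @param post_periods Number of post-adoption relative periods (0 = the
#'   adoption wave; later periods binned into `post_periods`).
#' @param reference Relative period omitted as the reference.
#' @param fixed_effects Fixed-effect factors. The event-study default adds
#'   region fixed effects to the time effects, the standard unit-and-time
#'   specification: with few adopting regions per cohort, unabsorbed
#'   region-level heterogeneity leaves each relative-time coefficient with a
#'   handful of effective clusters and anti-conservative bands. When
#'   `region_id` is absorbed the collinear ever-treated main effect is
#'   dropped automatically.
#' @param cluster Cluster column for the sandwich covariance, or `NULL`
#'   (the default here) for the classical covariance. Relative-time
#'   coefficients are identified from the handful of regions observed at
#'   each relative period, where the cluster sandwich is known to be
#'   anti-conservative; with region fixed effects absorbing the
#'   between-region heterogeneity, classical standard errors are the
#'   calibrated default, and randomization (placebo) inference is the
#'   recommended robustness check.
#' @return An `event_study` object: a data frame of periods, estimates and
#'   confidence bands plus the underlying `did_fit`.
#' @export
estimate_event_study <- function(panel, schedule,
                                 covariates = character(),
                                 outcome = "cancer",
                                 pre_periods = 2L,
                                 post_periods = 3L,
                                 reference = -1L,
                                 fixed_effects = c("wave", "region_id"),
                                 cluster = NULL,
                                 conf_level = 0.95) {
  if (reference < -pre_periods || reference > post_periods) {
    stop("reference period outside the requested event window", call. = FALSE)
  }
  waves <- sort(unique(panel$wave))
  if (length(waves) < 2L) stop("event study needs at least two waves",
                               call. = FALSE)
  panel <- build_treatment_indicator(panel, schedule)
  adoption <- schedule$adoption_year[match(panel$region_id,
                                           schedule$region_id)]
  # adoption wave = first wave at or after the adoption year
  adoption_idx <- vapply(adoption, function(a) {
    if (is.na(a)) NA_integer_ else {
      i <- which(waves >= a)
      if (length(i)) i[1L] else NA_integer_
    }
  }, integer(1))
  rel <- match(panel$wave, waves) - adoption_idx
  rel <- pmin(pmax(rel, -pre_periods), post_periods)

  periods <- seq.int(-pre_periods, post_periods)
  dummy_names <- character(0)
  empty_periods <- integer(0)
  for (p in setdiff(periods, reference)) {
    nm <- paste0("rel_", ifelse(p < 0, paste0("m", -p), p))
    d <- as.integer(!is.na(rel) & rel == p)
    if (sum(d) == 0L) {
      empty_periods <- c(empty_periods, p)
      next
    }
    panel[[nm]] <- d
    dummy_names <- c(dummy_names, nm)
  }
  if (length(empty_periods)) {
    message("relative period(s) without observations reported as NA: ",
            paste(empty_periods, collapse = ", "))
  }
  # the ever-treated main effect is collinear with region fixed effects
  base_terms <- if ("region_id" %in% fixed_effects) character(0) else "treat"
  spec <- model_spec(outcome, terms = c(base_terms, dummy_names),
                     covariates = covariates, fixed_effects = fixed_effects,
                     cluster = cluster, conf_level = conf_level)
  fit <- fit_linear(panel, spec)

  rows <- lapply(periods, function(p) {
    if (p == reference) {
      data.frame(period = p, estimate = 0, std_error = 0, p_value = NA_real_,
                 conf_low = 0, conf_high = 0, reference = TRUE)
    } else if (p %in% empty_periods) {
      data.frame(period = p, estimate = NA_real_, std_error = NA_real_,
                 p_value = NA_real_, conf_low = NA_real_,
                 conf_high = NA_real_, reference = FALSE)
    } else {
      nm <- paste0("rel_", ifelse(p < 0, paste0("m", -p), p))
      data.frame(period = p,
                 estimate = fit$coefficients[[nm]],
                 std_error = fit$se[[nm]],
                 p_value = fit$pvalue[[nm]],
                 conf_low = fit$conf_low[[nm]],
                 conf_high = fit$conf_high[[nm]],
                 reference = FALSE)
    }
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$period), ]
  rownames(curve) <- NULL
  out <- list(curve = curve, reference = reference, fit = fit,
              conf_level = conf_level)
  class(out) <- "event_study"
  out
}

#' @export
print.event_study <- function(x, ...) {
  cat(sprintf("Event study (reference period %d, %.0f%% bands)\n",
              x$reference, 100 * x$conf_level))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Plot an event-study curve
#'
#' Coefficients with confidence bands by relative period, the standard
#' parallel-trends diagnostic figure.
#'
#' @param object An `event_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_study <- function(object, ...) {
  cv <- object$curve[!is.na(object$curve$estimate), ]
  ggplot2::ggplot(cv, ggplot2::aes(x = period, y = estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = conf_low, ymax = conf_high),
                           width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Waves relative to adoption",
                  y = "Effect on incidence (per 1,000)",
                  title = "Event-study coefficients") +
    ggplot2::theme_minimal()
}

#' @export
plot.event_study <- function(x, ...) print(autoplot.event_study(x, ...))

#' Triple-interaction moderation model
#'
#' Fits `outcome = a0 + a1 * moderator + a2 * treat_post + a3 * treat_post *
#' moderator + lambda * X + time FE + e`. The coefficient on the interaction
#' column `treat_post_x_<moderator>` measures how the policy effect varies
#' per unit of the moderator (external pollution index or internal
#' depression score).
#'
#' If the moderator is identically zero the moderator and interaction
#' columns vanish and the fit degrades, with a message, to the plain DID
#' model; a non-zero constant moderator is an error (the interaction is
#' collinear with `treat_post`).
#'
#' @inheritParams estimate_did
#' @param moderator Name of the numeric moderator column.
#' @return A `did_fit` including the moderator main effect and the triple
#'   interaction.
#' @export
estimate_moderation <- function(panel, schedule, moderator,
                                covariates = character(),
                                outcome = "cancer",
                                fixed_effects = "wave",
                                cluster = "region_id",
                                conf_level = 0.95) {
  if (!moderator %in% names(panel)) {
    stop(sprintf("moderator column '%s' not found", moderator), call. = FALSE)
  }
  z <- panel[[moderator]]
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("moderator must be numeric and finite", call. = FALSE)
  }
  if (stats::var(z) == 0) {
    if (all(z == 0)) {
      message("moderator is identically zero; fitting the plain DID model")
      return(estimate_did(panel, schedule, covariates = covariates,
                          outcome = outcome, fixed_effects = fixed_effects,
                          cluster = cluster, conf_level = conf_level))
    }
    stop("zero-variance moderator: interaction is collinear with treat_post",
         call. = FALSE)
  }
  panel <- build_treatment_indicator(panel, schedule)
  if (sum(panel$treat_post) == 0L) {
    stop("no treated post-adoption observations; moderation not identified",
         call. = FALSE)
  }
  inter <- paste0("treat_post_x_", moderator)
  panel[[inter]] <- panel$treat_post * z
  spec <- model_spec(outcome,
                     terms = c(moderator, "treat", "treat_post", inter),
                     covariates = setdiff(covariates, moderator),
                     fixed_effects = fixed_effects, cluster = cluster,
                     conf_level = conf_level)
  fit <- fit_linear(panel, spec)
  attr(fit, "treatment_term") <- "treat_post"
  attr(fit, "interaction_term") <- inter
  fit
}

#' Combine event outcomes into a composite (pan-cancer) index
#'
#' Adds a column equal to 1,000 if any of the listed per-1,000 event columns
#' is positive for the record, else 0.
#'
#' @param panel Panel data frame.
#' @param cancer_columns Non-empty character vector of event columns.
#' @param name Name of the new column.
#' @return The panel with the composite column added.
#' @export
build_pan_cancer_outcome <- function(panel, cancer_columns,
                                     name = "pan_cancer") {
  if (length(cancer_columns) == 0L) {
    stop("cancer_columns must name at least one event outcome", call. = FALSE)
  }
  missing_cols <- setdiff(cancer_columns, names(panel))
  if (length(missing_cols)) {
    stop("outcome columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(panel[cancer_columns])
  if (!all(M %in% c(0, 1000))) {
    stop("event outcomes must be coded 0/1000 per record", call. = FALSE)
  }
  panel[[name]] <- 1000 * as.integer(rowSums(M > 0) > 0)
  panel
}

#' Per-outcome regression loop
#'
#' Runs the staggered DID once per outcome column (for example one model per
#' cancer site) and collects the treatment coefficients into a forest table.
#'
#' @inheritParams estimate_did
#' @param outcomes Character vector of outcome columns, fitted in order.
#' @return An `outcome_screen`: list of `did_fit`s plus a `table` of
#'   treatment estimates, intervals and p values per outcome.
#' @export
estimate_per_outcome <- function(panel, schedule, outcomes,
                                 covariates = character(),
                                 fixed_effects = "wave",
                                 cluster = "region_id",
                                 conf_level = 0.95) {
  stopifnot(length(outcomes) >= 1L)
  fits <- lapply(outcomes, function(oc) {
    estimate_did(panel, schedule, covariates = covariates, outcome = oc,
                 fixed_effects = fixed_effects, cluster = cluster,
                 conf_level = conf_level)
  })
  names(fits) <- outcomes
  tab <- do.call(rbind, lapply(outcomes, function(oc) {
    f <- fits[[oc]]
    data.frame(outcome = oc,
               estimate = f$coefficients[["treat_post"]],
               std_error = f$se[["treat_post"]],
               p_value = f$pvalue[["treat_post"]],
               conf_low = f$conf_low[["treat_post"]],
               conf_high = f$conf_high[["treat_post"]])
  }))
  rownames(tab) <- NULL
  out <- list(fits = fits, table = tab, conf_level = conf_level)
  class(out) <- "outcome_screen"
  out
}

#' @export
print.outcome_screen <- function(x, ...) {
  cat(sprintf("Per-outcome DID screen (%d outcomes)\n", nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Forest plot of per-outcome treatment effects
#'
#' @param object An `outcome_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_screen <- function(object, ...) {
  tab <- object$table
  tab$outcome <- factor(tab$outcome, levels = rev(tab$outcome))
  ggplot2::ggplot(tab, ggplot2::aes(x = estimate, y = outcome)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = conf_low, xmax = conf_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Treatment effect (per 1,000)", y = NULL,
                  title = "Policy effect by outcome") +
    ggplot2::theme_minimal()
}

#' @export
plot.outcome_screen <- function(x, ...) print(autoplot.outcome_screen(x, ...))

#' Chow test of coefficient equality across subsamples
#'
#' Fits the same specification on the pooled sample and within each group
#' and compares residual sums of squares:
#' `F = [(RSS_pooled - sum RSS_g) / ((G - 1) k)] / [sum RSS_g / (N - G k)]`
#' with `k` parameters per model, referred to the F distribution with
#' `(G - 1) k` and `N - G k` degrees of freedom.
#'
#' @param panel Panel data frame (must already contain the model columns,
#'   including any treatment indicator).
#' @param spec A [model_spec()] shared by the pooled and per-group fits; its
#'   columns must not be constant within any group.
#' @param grouping Name of the grouping column (>= 2 non-empty groups).
#' @return List with elements `statistic`, `p_value`, `df1`, `df2`,
#'   `rss_pooled`, `rss_groups`.
#' @export
chow_test <- function(panel, spec, grouping) {
  g <- panel[[grouping]]
  if (is.null(g)) stop(sprintf("grouping column '%s' not found", grouping),
                       call. = FALSE)
  groups <- split(seq_len(nrow(panel)), g)
  if (length(groups) < 2L) stop("grouping must define at least 2 groups",
                                call. = FALSE)
  pooled <- fit_linear(panel, spec)
  k <- pooled$n_params
  rss_g <- vapply(groups, function(idx) {
    f <- fit_linear(panel[idx, , drop = FALSE], spec)
    if (f$n_params != k) {
      stop("per-group design has a different dimension than the pooled design",
           call. = FALSE)
    }
    f$rss
  }, numeric(1))
  G <- length(groups)
  N <- pooled$n_obs
  df1 <- (G - 1) * k
  df2 <- N - G * k
  if (df2 <= 0) stop("insufficient residual degrees of freedom for the Chow test",
                     call. = FALSE)
  Fstat <- max(0, (pooled$rss - sum(rss_g)) / df1) / (sum(rss_g) / df2)
  list(statistic = Fstat,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2,
       rss_pooled = pooled$rss, rss_groups = rss_g)
}

#' Subgroup DID analysis with a Chow test
#'
#' Splits the panel by a grouping variable (binary column, or a numeric
#' column cut at `cutpoints` with labels like `"<18.5"`, `"18.5-25"`,
#' `">=25"`), fits the staggered DID within each group, and tests
#' coefficient equality across groups with a Chow test. The grouping
#' variable itself is dropped from the per-group covariate set (it is
#' constant or nearly so within groups). Groups with no treated post
#' observations are flagged and excluded from the Chow comparison.
#'
#' @inheritParams estimate_did
#' @param grouping Grouping column name.
#' @param cutpoints Optional numeric thresholds for cutting a continuous
#'   grouping variable.
#' @return A `subgroup_comparison`: per-group fits, a summary `table`, and
#'   the Chow `statistic`/`p_value`.
#' @export
subgroup_analysis <- function(panel, schedule, grouping,
                              cutpoints = NULL,
                              covariates = character(),
                              outcome = "cancer",
                              fixed_effects = "wave",
                              cluster = "region_id",
                              conf_level = 0.95) {
  if (!grouping %in% names(panel)) {
    stop(sprintf("grouping column '%s' not found", grouping), call. = FALSE)
  }
  if (!is.null(cutpoints)) {
    cp <- sort(cutpoints)
    labs <- c(sprintf("<%g", cp[1]),
              if (length(cp) > 1)
                sprintf("%g-%g", cp[-length(cp)], cp[-1]) else NULL,
              sprintf(">=%g", cp[length(cp)]))
    gvar <- cut(panel[[grouping]], breaks = c(-Inf, cp, Inf),
                labels = labs, right = FALSE)
  } else {
    gvar <- factor(panel[[grouping]])
  }
  if (nlevels(droplevels(gvar)) < 2L) {
    stop("grouping must partition the panel into at least 2 non-empty groups",
         call. = FALSE)
  }
  panel$.group <- gvar
  panel <- build_treatment_indicator(panel, schedule)
  covs <- setdiff(covariates, grouping)

  levels_used <- levels(droplevels(gvar))
  fits <- list()
  estimable <- logical(length(levels_used))
  names(estimable) <- levels_used
  for (lv in levels_used) {
    sub <- panel[panel$.group == lv, , drop = FALSE]
    if (sum(sub$treat_post) == 0L) {
      fits[[lv]] <- NULL
      estimable[lv] <- FALSE
      message(sprintf("group '%s' has no treated observations; fit skipped",
                      lv))
      next
    }
    # drop covariates constant within the group (would be collinear)
    keep <- covs[vapply(covs, function(cv) stats::var(sub[[cv]]) > 0,
                        logical(1))]
    fits[[lv]] <- estimate_did(sub, schedule, covariates = keep,
                               outcome = outcome,
                               fixed_effects = fixed_effects,
                               cluster = cluster, conf_level = conf_level)
    estimable[lv] <- TRUE
  }
  if (!any(estimable)) stop("no subgroup is estimable", call. = FALSE)

  tab <- do.call(rbind, lapply(levels_used[estimable], function(lv) {
    f <- fits[[lv]]
    data.frame(group = lv,
               estimate = f$coefficients[["treat_post"]],
               conf_low = f$conf_low[["treat_post"]],
               conf_high = f$conf_high[["treat_post"]],
               p_value = f$pvalue[["treat_post"]],
               n = f$n_obs)
  }))
  rownames(tab) <- NULL

  # Chow test restricted to the estimable groups, common reduced covariates
  if (sum(estimable) < 2L) {
    message("fewer than 2 estimable groups; Chow test not available")
    out <- list(grouping = grouping, fits = fits, table = tab,
                chow_statistic = NA_real_, chow_p_value = NA_real_,
                chow = NULL, estimable = estimable)
    class(out) <- "subgroup_comparison"
    return(out)
  }
  est_rows <- panel$.group %in% levels_used[estimable]
  chow_panel <- panel[est_rows, , drop = FALSE]
  chow_panel$.group <- droplevels(chow_panel$.group)
  common_covs <- covs[vapply(covs, function(cv) {
    all(tapply(chow_panel[[cv]], chow_panel$.group, stats::var) > 0)
  }, logical(1))]
  chow_spec <- model_spec(outcome, terms = c("treat", "treat_post"),
                          covariates = common_covs,
                          fixed_effects = fixed_effects, cluster = cluster,
                          conf_level = conf_level)
  chow <- chow_test(chow_panel, chow_spec, ".group")

  out <- list(grouping = grouping, fits = fits, table = tab,
              chow_statistic = chow$statistic, chow_p_value = chow$p_value,
              chow = chow, estimable = estimable)
  class(out) <- "subgroup_comparison"
  out
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("Subgroup DID analysis by %s\n", x$grouping))
  print(x$table, row.names = FALSE)
  cat(sprintf("Chow test: F = %.3f (df %d, %d), p = %.4g\n",
              x$chow_statistic, x$chow$df1, x$chow$df2, x$chow_p_value))
  invisible(x)
}
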