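test_that("two-period simultaneous adoption reduces to the four-cell DID", {
  fx <- make_2x2_panel(seed = 21)
  f <- estimate_did(fx$panel, fx$schedule)
  pan <- build_treatment_indicator(fx$panel, fx$schedule)
  cell <- function(tr, post) {
    mean(pan$cancer[pan$treat == tr & (pan$wave == 2015) == post])
  }
  did_by_means <- (cell(1, TRUE) - cell(1, FALSE)) -
    (cell(0, TRUE) - cell(0, FALSE))
  expect_equal(unname(coef(f)[["treat_post"]]), did_by_means,
               tolerance = 1e-8)
})

test_that("estimate_did requires treated post observations", {
  cfg <- small_cfg(treated_cohorts = data.frame(adoption_year = integer(),
                                                n_regions = integer()))
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  expect_error(estimate_did(pan, sch), "no treated")
})

test_that("estimates are invariant to record order and region relabeling", {
  cfg <- small_cfg(seed = 22L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  base <- coef(estimate_did(pan, sch, covariates = c("gender", "age")))

  shuffled <- pan[withr::with_seed(1, sample(nrow(pan))), ]
  expect_equal(coef(estimate_did(shuffled, sch,
                                 covariates = c("gender", "age"))),
               base, tolerance = 1e-9)

  relabel <- setNames(sprintf("Z%03d", seq_along(unique(pan$region_id))),
                      sort(unique(pan$region_id)))
  pan2 <- pan
  pan2$region_id <- unname(relabel[pan$region_id])
  sch2 <- sch
  sch2$region_id <- unname(relabel[sch$region_id])
  f2 <- estimate_did(pan2, sch2, covariates = c("gender", "age"))
  expect_equal(unname(coef(f2)[["treat_post"]]),
               unname(base[["treat_post"]]), tolerance = 1e-9)
})

test_that("per-outcome loop preserves order, matches single fits, and screens signal", {
  cfg <- cohort_config(n_regions = 60, n_individuals_per_region = 100,
                       treatment_effect = 0, moderation_effect = 0,
                       seed = 31L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  oc <- data.frame(name = sprintf("oc%d", 1:8), baseline = 15,
                   tau = c(rep(-16, 4), rep(0, 4)))
  pan <- add_event_outcomes(pan, sch, oc, seed = 5)

  sc <- estimate_per_outcome(pan, sch, outcomes = oc$name)
  expect_equal(sc$table$outcome, oc$name)
  expect_equal(unname(sc$table$estimate[1]),
               unname(coef(estimate_did(pan, sch,
                                        outcome = "oc1"))[["treat_post"]]),
               tolerance = 1e-12)
  # outcomes carrying a true negative effect are flagged, null ones mostly not
  expect_true(all(sc$table$p_value[1:4] < 0.05))
  expect_lte(sum(sc$table$p_value[5:8] < 0.05), 2)
  expect_s3_class(autoplot(sc), "ggplot")
})

test_that("pan-cancer index flags any listed event and only those", {
  six <- c("endometrial", "cervical", "gastric", "esophageal", "breast",
           "lung")
  pan <- as.data.frame(setNames(rep(list(c(0, 0, 0)), 7), c(six, "liver")))
  pan[2, "cervical"] <- 1000   # cervical cancer only
  pan[3, "liver"] <- 1000      # a cancer outside the list
  out <- build_pan_cancer_outcome(pan, six)
  expect_equal(out$pan_cancer, c(0, 1000, 0))
  expect_error(build_pan_cancer_outcome(pan, character()), "at least one")
  expect_error(build_pan_cancer_outcome(transform(pan, cervical = 7), six),
               "0/1000")
  # all-zero outcomes give an all-zero index
  expect_true(all(build_pan_cancer_outcome(pan[1, , drop = FALSE],
                                           six)$pan_cancer == 0))
})

test_that("moderation model recovers its degenerate and collinear cases", {
  cfg <- small_cfg(seed = 23L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)

  pan$zero_mod <- 0
  expect_message(f0 <- estimate_moderation(pan, sch, "zero_mod",
                                           covariates = c("gender")),
                 "identically zero")
  f1 <- estimate_did(pan, sch, covariates = c("gender"))
  expect_equal(coef(f0), coef(f1), tolerance = 1e-12)

  pan$const_mod <- 5
  expect_error(estimate_moderation(pan, sch, "const_mod"), "zero-variance")
  pan$bad <- NA_real_
  expect_error(estimate_moderation(pan, sch, "bad"), "finite")
  expect_error(estimate_moderation(pan, sch, "not_there"), "not found")

  # interaction term present and labeled, treat_post retained
  fm <- estimate_moderation(pan, sch, "cesd", covariates = c("gender"))
  expect_true(all(c("cesd", "treat_post", "treat_post_x_cesd") %in%
                    names(coef(fm))))
})

test_that("event-study contract: reference period, sorting, window errors", {
  cfg <- small_cfg(n_individuals_per_region = 60, seed = 24L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  suppressMessages(es <- estimate_event_study(pan, sch))
  cv <- es$curve
  expect_equal(cv$period, sort(cv$period))
  ref <- cv[cv$reference, ]
  expect_equal(ref$period, -1)
  expect_equal(ref$estimate, 0)
  expect_equal(ref$conf_high - ref$conf_low, 0)
  expect_error(estimate_event_study(pan, sch, reference = -5),
               "outside the requested")
  expect_s3_class(autoplot(es), "ggplot")
})

test_that("event study separates pre and post periods under a real effect", {
  cfg <- cohort_config(n_regions = 80, n_individuals_per_region = 200,
                       treatment_effect = -47.2, moderation_effect = 0,
                       seed = 25L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  suppressMessages(es <- estimate_event_study(pan, sch,
                                              covariates = c("gender", "age")))
  cv <- es$curve[!is.na(es$curve$estimate), ]
  pre <- cv[cv$period < 0 & !cv$reference, ]
  post <- cv[cv$period >= 1, ]
  expect_true(all(pre$conf_low <= 0 & 0 <= pre$conf_high))
  expect_true(all(post$p_value < 0.01))
  expect_true(all(post$estimate < 0))
})

test_that("post-period event-study coefficients aggregate to the DID estimate", {
  cfg <- cohort_config(n_individuals_per_region = 200,
                       treatment_effect = -40, moderation_effect = 0,
                       seed = 26L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)
  did <- estimate_did(pan, sch, fixed_effects = c("wave", "region_id"),
                      cluster = NULL)
  suppressMessages(es <- estimate_event_study(pan, sch))
  cv <- es$curve[es$curve$period >= 0 & !is.na(es$curve$estimate), ]

  pan2 <- build_treatment_indicator(pan, sch)
  waves <- sort(unique(pan$wave))
  adoption <- sch$adoption_year[match(pan2$region_id, sch$region_id)]
  ai <- vapply(adoption, function(a) if (is.na(a)) NA_integer_
               else which(waves >= a)[1], integer(1))
  rel <- pmin(pmax(match(pan2$wave, waves) - ai, -2L), 3L)
  wts <- table(factor(rel[!is.na(rel) & rel >= 0], levels = cv$period))
  avg <- sum(cv$estimate * as.numeric(wts)) / sum(wts)
  expect_lt(abs(avg - coef(did)[["treat_post"]]), 10)
})

test_that("Chow statistic reproduces a hand-computed two-group example", {
  # 10 rows, 2 groups; oracle from lm() residual sums of squares
  d <- data.frame(y = c(1, 2, 3, 5, 4, 9, 8, 12, 11, 15),
                  x = c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4),
                  g = rep(c("a", "b"), each = 5))
  spec <- model_spec("y", terms = "x", fixed_effects = character(),
                     cluster = NULL)
  res <- chow_test(d, spec, "g")
  rss <- function(sub) sum(resid(lm(y ~ x, data = sub))^2)
  rss_p <- rss(d); rss_a <- rss(d[d$g == "a", ]); rss_b <- rss(d[d$g == "b", ])
  k <- 2; G <- 2; N <- 10
  Fref <- ((rss_p - rss_a - rss_b) / ((G - 1) * k)) /
    ((rss_a + rss_b) / (N - G * k))
  expect_equal(res$statistic, Fref, tolerance = 1e-10)
  expect_equal(res$p_value, pf(Fref, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # duplicating one group as both subgroups: F = 0, p = 1
  dup <- rbind(transform(d[d$g == "a", ], g = "a"),
               transform(d[d$g == "a", ], g = "b"))
  res0 <- chow_test(dup, spec, "g")
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-10)
})

test_that("Chow test detects opposite-signed treatment effects", {
  withr::with_seed(27, {
    n <- 4000
    make_group <- function(tau, label) {
      d <- data.frame(region_id = sample(sprintf("%s%02d", label, 1:20),
                                         n, TRUE),
                      wave = sample(c(2011, 2015), n, TRUE))
      d$treat <- as.integer(d$region_id %in%
                              sprintf("%s%02d", label, 1:8))
      d$treat_post <- d$treat * (d$wave == 2015)
      d$y <- 100 + tau * d$treat_post + rnorm(n, 0, 30)
      d$g <- label
      d
    }
    d <- rbind(make_group(40, "A"), make_group(-40, "B"))
    spec <- model_spec("y", terms = c("treat", "treat_post"),
                       fixed_effects = "wave", cluster = NULL)
    res <- chow_test(d, spec, "g")
    expect_lt(res$p_value, 0.001)
  })
})

test_that("subgroup analysis cuts, labels, fits and flags correctly", {
  cfg <- small_cfg(n_individuals_per_region = 80, seed = 28L)
  sch <- generate_policy_schedule(cfg)
  pan <- generate_panel(cfg, sch)

  sg <- subgroup_analysis(pan, sch, "bmi", cutpoints = c(18.5, 25),
                          covariates = c("gender", "age", "bmi"))
  expect_setequal(sg$table$group, c("<18.5", "18.5-25", ">=25"))
  expect_equal(sum(sg$table$n), nrow(pan))
  expect_true(is.finite(sg$chow_statistic))
  expect_gte(sg$chow_p_value, 0)

  # binary grouping drops the grouping covariate from per-group fits
  sg2 <- subgroup_analysis(pan, sch, "gender",
                           covariates = c("gender", "age"))
  expect_false("gender" %in% names(coef(sg2$fits[["0"]])))
  expect_error(subgroup_analysis(pan, sch, "nope"), "not found")

  # a group without treated observations is flagged and skipped
  pan$odd <- as.integer(pan$region_id %in%
                          sch$region_id[!is.na(sch$adoption_year)])
  expect_message(sg3 <- subgroup_analysis(pan, sch, "odd",
                                          covariates = c("age")),
                 "no treated observations")
  expect_equal(nrow(sg3$table), 1)
})
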