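test_that("treatment indicator follows the adoption calendar inclusively", {
  pan <- data.frame(region_id = "A", wave = c(2011, 2013, 2015, 2018))
  sch <- data.frame(region_id = c("A", "B"),
                    adoption_year = c(2014L, NA_integer_))
  out <- build_treatment_indicator(pan, sch)
  expect_equal(out$treat_post, c(0, 0, 1, 1))
  expect_equal(out$treat, rep(1, 4))

  never <- build_treatment_indicator(
    data.frame(region_id = "B", wave = c(2011, 2018)), sch)
  expect_equal(never$treat_post, c(0, 0))

  boundary <- build_treatment_indicator(
    data.frame(region_id = "A", wave = 2014), sch)
  expect_equal(boundary$treat_post, 1)

  expect_message(
    miss <- build_treatment_indicator(
      data.frame(region_id = "Z", wave = 2015), sch),
    "never-treated")
  expect_equal(miss$treat_post, 0)
})

test_that("fit_linear solves the normal equations on hand-checked examples", {
  d <- data.frame(y = c(0, 2, 3, 5), x = c(0, 0, 1, 1))
  f <- fit_linear(d, model_spec("y", terms = "x",
                                fixed_effects = character(), cluster = NULL))
  expect_equal(unname(coef(f)[["x"]]), 3, tolerance = 1e-12)
  expect_equal(unname(coef(f)[["(Intercept)"]]), 1, tolerance = 1e-12)

  # constant outcome: zero slopes, intercept at the constant, R^2 = 0
  dc <- data.frame(y = rep(7, 10), x = rnorm(10))
  fc <- fit_linear(dc, model_spec("y", terms = "x",
                                  fixed_effects = character(),
                                  cluster = NULL))
  expect_equal(unname(coef(fc)), c(7, 0), tolerance = 1e-10)
  expect_equal(fc$r_squared, 0)
})

test_that("coefficients match an independent pseudo-inverse oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(20:60, 1)
      p <- sample(2:5, 1)
      X <- cbind(1, matrix(rnorm(n * p), n))
      y <- rnorm(n)
      d <- as.data.frame(X[, -1, drop = FALSE])
      names(d) <- paste0("x", seq_len(p))
      d$y <- y
      f <- fit_linear(d, model_spec("y", terms = names(d)[seq_len(p)],
                                    fixed_effects = character(),
                                    cluster = NULL))
      oracle <- pinv_coef(X, y)
      expect_lt(max(abs(unname(coef(f)) - oracle)) /
                  max(abs(oracle)), 1e-10)
    }
  })
})

test_that("cluster sandwich matches the reference implementation and the HC identity", {
  withr::with_seed(12, {
    d <- data.frame(y = rnorm(80), x = rnorm(80), z = rnorm(80),
                    g = rep(1:16, each = 5))
    f <- fit_linear(d, model_spec("y", terms = c("x", "z"),
                                  fixed_effects = character(), cluster = "g"))
    lmf <- stats::lm(y ~ x + z, data = d)
    expect_equal(unname(vcov(f)),
                 unname(sandwich::vcovCL(lmf, cluster = d$g, type = "HC1")),
                 tolerance = 1e-10)

    # one observation per cluster: cluster sandwich = HC1 heteroskedasticity
    # sandwich (the small-sample factors coincide at G = N)
    d1 <- data.frame(y = rnorm(50), x = rnorm(50), g = 1:50)
    f1 <- fit_linear(d1, model_spec("y", terms = "x",
                                    fixed_effects = character(),
                                    cluster = "g"))
    lm1 <- stats::lm(y ~ x, data = d1)
    expect_equal(unname(vcov(f1)),
                 unname(sandwich::vcovHC(lm1, type = "HC1")),
                 tolerance = 1e-10)
  })
})

test_that("large-design solver path agrees with the QR path", {
  withr::with_seed(13, {
    n <- 5000
    d <- data.frame(y = rnorm(n), x = rnorm(n),
                    g = factor(sample(letters[1:20], n, TRUE)),
                    region_id = sample(sprintf("R%02d", 1:12), n, TRUE))
    spec <- model_spec("y", terms = "x", fixed_effects = "g",
                       cluster = "region_id")
    f_qr <- fit_linear(d, spec)
    # force the normal-equations path by shrinking the threshold via a big
    # design: replicate columns of dummies through a second factor
    d$g2 <- factor(sample(LETTERS[1:24], n, TRUE))
    spec2 <- model_spec("y", terms = "x", fixed_effects = c("g", "g2"),
                        cluster = "region_id")
    f2 <- fit_linear(d, spec2)
    lmf <- stats::lm(y ~ x + g + g2, data = d)
    expect_equal(unname(coef(f2)[["x"]]), unname(coef(lmf)[["x"]]),
                 tolerance = 1e-8)
    expect_equal(unname(coef(f_qr)[["x"]]),
                 unname(coef(stats::lm(y ~ x + g, data = d))[["x"]]),
                 tolerance = 1e-10)
  })
})

test_that("dummy-expanded fixed effects equal explicit within-demeaning", {
  cfg <- small_cfg(n_regions = 15, n_individuals_per_region = 30, seed = 14L)
  sch <- generate_policy_schedule(cfg)
  pan <- build_treatment_indicator(generate_panel(cfg, sch), sch)
  f <- fit_linear(pan, model_spec("cancer", terms = c("treat", "treat_post"),
                                  covariates = c("gender", "age"),
                                  fixed_effects = "wave", cluster = NULL))
  # Frisch-Waugh-Lovell: demean outcome and regressors by wave, no intercept
  dm <- function(v) v - stats::ave(v, pan$wave)
  Xd <- cbind(treat = dm(pan$treat), treat_post = dm(pan$treat_post),
              gender = dm(pan$gender), age = dm(pan$age))
  bd <- qr.coef(qr(Xd), dm(pan$cancer))
  expect_equal(unname(coef(f)[c("treat", "treat_post", "gender", "age")]),
               unname(bd), tolerance = 1e-8)
})

test_that("observation weights behave like frequency replication", {
  withr::with_seed(15, {
    d <- data.frame(y = rnorm(30), x = rnorm(30))
    d$w <- sample(1:3, 30, TRUE)
    drep <- d[rep(seq_len(30), d$w), ]
    fw <- fit_linear(d, model_spec("y", terms = "x",
                                   fixed_effects = character(),
                                   cluster = NULL, weights = "w"))
    fr <- fit_linear(drep, model_spec("y", terms = "x",
                                      fixed_effects = character(),
                                      cluster = NULL))
    expect_equal(coef(fw), coef(fr), tolerance = 1e-10)
  })
})

test_that("degenerate designs and inputs raise informative errors", {
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  d$x2 <- 2 * d$x
  expect_error(fit_linear(d, model_spec("y", terms = c("x", "x2"),
                                        fixed_effects = character(),
                                        cluster = NULL)),
               "rank deficient.*x2")
  d$g <- 1
  expect_error(fit_linear(d, model_spec("y", terms = "x",
                                        fixed_effects = character(),
                                        cluster = "g")),
               "at least 2 clusters")
  d$w <- c(-1, rep(1, 19))
  expect_error(fit_linear(d, model_spec("y", terms = "x",
                                        fixed_effects = character(),
                                        cluster = NULL, weights = "w")),
               "positive")
  expect_error(fit_linear(d, model_spec("y", terms = "missing_col",
                                        fixed_effects = character(),
                                        cluster = NULL)),
               "missing")
})

test_that("Wald intervals are consistent, monotone and match published formatting", {
  withr::with_seed(16, {
    d <- data.frame(y = rnorm(40), x = rnorm(40))
    f <- fit_linear(d, model_spec("y", terms = "x",
                                  fixed_effects = character(),
                                  cluster = NULL))
    wi95 <- wald_interval(f, "x", 0.95)
    wi999 <- wald_interval(f, "x", 0.999)
    expect_lt(wi999[["conf_low"]], wi95[["conf_low"]])
    expect_gt(wi999[["conf_high"]], wi95[["conf_high"]])
    expect_equal(wi95[["conf_low"]], f$conf_low[["x"]], tolerance = 1e-12)
    expect_error(wald_interval(f, "nope"), "unknown term")

    # degenerate SE gives a point interval
    dc <- data.frame(y = rep(3, 10), x = rnorm(10))
    fc <- fit_linear(dc, model_spec("y", terms = "x",
                                    fixed_effects = character(),
                                    cluster = NULL))
    wic <- wald_interval(fc, "(Intercept)")
    expect_equal(unname(wic), rep(3, 3), tolerance = 1e-10)
  })

  # published-style contract: estimate -47.200 with SE and df chosen so the
  # 95% interval prints as [-61.103, -33.296]
  half <- (61.103 - 33.296) / 2
  df <- 34000
  fmock <- structure(list(coefficients = c(tp = -(61.103 + 33.296) / 2),
                          se = c(tp = half / stats::qt(0.975, df)),
                          df = df), class = "did_fit")
  wi <- wald_interval(fmock, "tp", 0.95)
  expect_equal(unname(wi[["conf_low"]]), -61.103, tolerance = 1e-3)
  expect_equal(unname(wi[["conf_high"]]), -33.296, tolerance = 1e-3)
})

test_that("fit table and JSON serialization expose the published columns", {
  d <- data.frame(y = rnorm(25), x = rnorm(25))
  f <- fit_linear(d, model_spec("y", terms = "x",
                                fixed_effects = character(), cluster = NULL))
  tab <- fit_table(f)
  expect_named(tab, c("term", "estimate", "std_error", "statistic",
                      "p_value", "conf_low", "conf_high"))
  path <- file.path(tempdir(), "fit.json")
  write_fit_json(f, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$table$estimate, tab$estimate, tolerance = 1e-12)
  expect_equal(parsed$n_obs, 25)
  unlink(path)
})
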