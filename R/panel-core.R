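# Shared linear-model engine: design-matrix construction, fixed-effect
# absorption via dummy expansion, OLS, and cluster-robust covariance.

#' Specify a linear probability model on a panel
#'
#' @param outcome Name of the outcome column (per-1,000 event coding).
#' @param terms Character vector of treatment/interaction columns, placed
#'   first in the design and in printed tables.
#' @param covariates Character vector of control-variable columns.
#' @param fixed_effects Character vector of factor columns absorbed by dummy
#'   expansion (first level dropped as the reference). Default: wave (time)
#'   fixed effects only.
#' @param cluster Column defining the clustering of the sandwich covariance,
#'   or `NULL` for the classical OLS covariance. Default `"region_id"`: the
#'   policy varies at region level.
#' @param weights Optional name of a positive observation-weight column.
#' @param conf_level Confidence level for reported intervals.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome,
                       terms = c("treat", "treat_post"),
                       covariates = character(),
                       fixed_effects = "wave",
                       cluster = "region_id",
                       weights = NULL,
                       conf_level = 0.95) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            conf_level > 0, conf_level < 1)
  spec <- list(outcome = outcome, terms = terms, covariates = covariates,
               fixed_effects = fixed_effects, cluster = cluster,
               weights = weights, conf_level = conf_level)
  class(spec) <- "model_spec"
  spec
}

#' Add the staggered treatment indicator to a panel
#'
#' Adds `treat` (1 for regions ever in the pilot) and the core explanatory
#' variable `treat_post` (1 if the region is a pilot and the wave year is at
#' or after its adoption year, else 0). Regions present in the panel but
#' absent from the schedule are treated as never-treated, with a message.
#'
#' @param panel A panel data frame with `region_id` and `wave`.
#' @param schedule A `policy_schedule` data frame (`region_id`,
#'   `adoption_year`, `NA` = never treated).
#' @return The panel with `treat` and `treat_post` columns.
#' @examples
#' pan <- data.frame(region_id = "A", wave = c(2011, 2013, 2015, 2018))
#' sch <- data.frame(region_id = "A", adoption_year = 2014)
#' build_treatment_indicator(pan, sch)$treat_post  # 0, 0, 1, 1
#' @export
build_treatment_indicator <- function(panel, schedule) {
  stopifnot(all(c("region_id", "wave") %in% names(panel)))
  m <- match(panel$region_id, schedule$region_id)
  if (anyNA(m)) {
    missing_regions <- unique(panel$region_id[is.na(m)])
    message(sprintf(
      "%d region(s) absent from the schedule treated as never-treated: %s",
      length(missing_regions),
      paste(utils::head(missing_regions, 5), collapse = ", ")))
  }
  adoption <- schedule$adoption_year[m]
  panel$treat <- as.integer(!is.na(adoption))
  panel$treat_post <- as.integer(panel$treat == 1L & panel$wave >= adoption)
  panel$treat_post[is.na(panel$treat_post)] <- 0L
  panel
}

# Design matrix: intercept + terms + covariates + FE dummies (reference =
# first level in sort order, dropped).
.build_design <- function(panel, spec) {
  cols <- c(spec$outcome, spec$terms, spec$covariates, spec$fixed_effects,
            spec$cluster, spec$weights)
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols)) {
    stop("columns missing from panel: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(panel)
  blocks <- list(`(Intercept)` = rep(1, n))
  for (nm in c(spec$terms, spec$covariates)) {
    v <- panel[[nm]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' must be numeric", nm), call. = FALSE)
    }
    blocks[[nm]] <- v
  }
  fe_blocks <- list()
  for (fe in spec$fixed_effects) {
    f <- factor(panel[[fe]])
    if (nlevels(f) > 1L) {
      D <- matrix(0, n, nlevels(f) - 1L,
                  dimnames = list(NULL, paste0(fe, levels(f)[-1L])))
      idx <- as.integer(f)
      nonref <- which(idx > 1L)
      D[cbind(nonref, idx[nonref] - 1L)] <- 1
      fe_blocks[[fe]] <- D
    }
  }
  do.call(cbind, c(blocks, fe_blocks))
}

#' Fit a linear model by ordinary least squares
#'
#' The workhorse behind every regression in the package: a linear
#' probability model of a per-1,000 event outcome on treatment terms,
#' controls and fixed-effect dummies, with either the classical or the
#' cluster-robust sandwich covariance. The cluster sandwich uses the
#' small-sample factor `G/(G-1) * (N-1)/(N-K)` and `G - 1` degrees of
#' freedom for t statistics and intervals (`N - K` without clustering).
#'
#' @param panel A panel data frame.
#' @param spec A [model_spec()].
#' @return A `did_fit` object: coefficient estimates, covariance matrix,
#'   standard errors, t and two-sided p values, confidence intervals,
#'   `n_obs`, `n_clusters`, `r_squared`, `rss` and residual df.
#' @examples
#' d <- data.frame(y = c(0, 2, 3, 5), x = c(0, 0, 1, 1))
#' f <- fit_linear(d, model_spec("y", terms = "x",
#'                               fixed_effects = character(), cluster = NULL))
#' coef(f)  # intercept 1, slope 3
#' @export
fit_linear <- function(panel, spec) {
  X <- .build_design(panel, spec)
  y <- panel[[spec$outcome]]
  w <- if (is.null(spec$weights)) rep(1, nrow(X)) else panel[[spec$weights]]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("observation weights must be positive and finite", call. = FALSE)
  }

  n <- nrow(X)
  k <- ncol(X)
  XtWX <- crossprod(X, X * w)

  # QR on the full design for small problems (best accuracy); Cholesky on
  # the normal equations for large dummy-expanded designs (the designs here
  # are well conditioned: 0/1 dummies and bounded covariates)
  if (n * k^2 <= 2e8) {
    qx <- qr(X * sqrt(w))
    if (qx$rank < k) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- stats::lm.wfit(X, y, w)$coefficients
  } else {
    qn <- qr(XtWX)
    if (qn$rank < k) {
      bad <- colnames(X)[qn$pivot[(qn$rank + 1L):k]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- drop(solve(qn, crossprod(X, w * y)))
    names(beta) <- colnames(X)
  }
  res <- y - drop(X %*% beta)
  rss <- sum(w * res^2)
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0

  XtWX_inv <- chol2inv(chol(XtWX))
  dimnames(XtWX_inv) <- list(colnames(X), colnames(X))

  if (!is.null(spec$cluster)) {
    g <- panel[[spec$cluster]]
    G <- length(unique(g))
    if (G < 2L) stop("cluster-robust variance needs at least 2 clusters",
                     call. = FALSE)
    score <- X * (w * res)
    meat <- crossprod(rowsum(score, group = g, reorder = FALSE))
    adj <- (G / (G - 1)) * ((n - 1) / (n - k))
    vcov <- adj * XtWX_inv %*% meat %*% XtWX_inv
    df <- G - 1
  } else {
    G <- NA_integer_
    sigma2 <- rss / (n - k)
    vcov <- sigma2 * XtWX_inv
    df <- n - k
  }
  vcov <- (vcov + t(vcov)) / 2  # enforce symmetry

  se <- sqrt(pmax(diag(vcov), 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  crit <- stats::qt(1 - (1 - spec$conf_level) / 2, df = df)

  out <- list(
    coefficients = beta,
    vcov = vcov,
    se = se,
    tstat = tstat,
    pvalue = pval,
    conf_low = beta - crit * se,
    conf_high = beta + crit * se,
    conf_level = spec$conf_level,
    df = df,
    n_obs = n,
    n_clusters = G,
    r_squared = r2,
    rss = rss,
    n_params = k,
    spec = spec
  )
  class(out) <- "did_fit"
  out
}

#' Wald confidence interval for a single coefficient
#'
#' @param fit A `did_fit`.
#' @param term Coefficient name.
#' @param level Confidence level.
#' @return Named numeric vector `c(estimate, conf_low, conf_high)`.
#' @export
wald_interval <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "did_fit"), level > 0, level < 1)
  if (!term %in% names(fit$coefficients)) {
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  }
  est <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  crit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  c(estimate = est, conf_low = est - crit * se, conf_high = est + crit * se)
}

#' @export
coef.did_fit <- function(object, ...) object$coefficients

#' @export
vcov.did_fit <- function(object, ...) object$vcov

#' Tidy coefficient table of a fit
#'
#' @param fit A `did_fit`.
#' @return A data frame with one row per coefficient: estimate, SE,
#'   t statistic, p value and confidence bounds.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "did_fit"))
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    std_error = unname(fit$se),
    statistic = unname(fit$tstat),
    p_value = unname(fit$pvalue),
    conf_low = unname(fit$conf_low),
    conf_high = unname(fit$conf_high),
    row.names = NULL
  )
}

#' @export
print.did_fit <- function(x, digits = 3, ...) {
  tab <- fit_table(x)
  # treatment terms first, fixed-effect dummies and intercept last, mirroring
  # the conventional published layout (coef [95% CI], p, R^2, N)
  fe_pat <- paste0("^(", paste(c(x$spec$fixed_effects, "\\(Intercept"),
                               collapse = "|"), ")")
  ord <- order(grepl(fe_pat, tab$term))
  tab <- tab[ord, ]
  cat(sprintf("Linear probability fit: %s (per 1,000)\n", x$spec$outcome))
  disp <- data.frame(
    term = tab$term,
    coef = sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
                   tab$estimate, tab$conf_low, tab$conf_high),
    p = ifelse(tab$p_value < 0.001, "<0.001",
               sprintf("%.3f", tab$p_value))
  )
  print(disp, row.names = FALSE, right = FALSE)
  cat(sprintf("R2 %.4f   N %d%s\n", x$r_squared, x$n_obs,
              if (!is.na(x$n_clusters))
                sprintf("   clusters %d (cluster-robust SE)", x$n_clusters)
              else ""))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `did_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(table = fit_table(fit), r_squared = fit$r_squared,
         n_obs = fit$n_obs, n_clusters = fit$n_clusters,
         conf_level = fit$conf_level),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
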