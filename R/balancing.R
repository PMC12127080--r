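# Covariate balancing for the robustness analyses: entropy balancing solved
# as a constrained minimum-divergence problem through its dual, plus
# logistic propensity scores (IRLS) and nearest-neighbour caliper matching.

#' Entropy balancing weights
#'
#' Finds control-unit weights that minimize the Kullback--Leibler divergence
#' from the base weights subject to exact moment constraints: the weighted
#' control means (order 1; plus raw second moments for order 2) equal the
#' treated sample moments. The solution has the exponential-tilting form
#' `w_i = q_i * exp(c_i' lambda)` (up to normalization) and is found by
#' Newton iteration on the dual with step halving; convergence is declared
#' when the maximum absolute constraint violation falls below `tol`.
#' Weights are normalized to sum to the number of treated units.
#'
#' @param treated Numeric matrix (or data frame) of treated-unit covariates.
#' @param control Numeric matrix (or data frame) of control-unit covariates,
#'   same columns.
#' @param moment_order 1 balances means; 2 additionally balances raw second
#'   moments (hence variances, given matched means).
#' @param base_weights Positive base weights for the control units (default
#'   uniform).
#' @param tol Convergence tolerance on the maximum constraint violation.
#' @param max_iter Newton iteration cap.
#' @return A `balance_weights` object: `weights` (one per control unit,
#'   strictly positive), `converged`, `iterations`, `max_violation`,
#'   `lambda`, and the `targets` matched.
#' @examples
#' tr <- cbind(x = c(1, 2))
#' ct <- cbind(x = c(0, 1, 2))
#' w <- entropy_balance(tr, ct)
#' weighted.mean(ct[, 1], w$weights)  # 1.5 = treated mean
#' @export
entropy_balance <- function(treated, control, moment_order = 1L,
                            base_weights = NULL, tol = 1e-8,
                            max_iter = 200L) {
  Xt <- as.matrix(treated)
  Xc <- as.matrix(control)
  if (ncol(Xt) != ncol(Xc)) {
    stop("treated and control matrices must share columns", call. = FALSE)
  }
  stopifnot(moment_order %in% c(1L, 2L))
  if (is.null(colnames(Xc))) {
    colnames(Xc) <- colnames(Xt) <- paste0("x", seq_len(ncol(Xc)))
  }
  if (moment_order == 2L) {
    Xt <- cbind(Xt, `colnames<-`(Xt^2, paste0(colnames(Xt), "^2")))
    Xc <- cbind(Xc, `colnames<-`(Xc^2, paste0(colnames(Xc), "^2")))
  }
  n_c <- nrow(Xc)
  n_t <- nrow(Xt)
  q <- if (is.null(base_weights)) rep(1 / n_c, n_c) else {
    if (any(base_weights <= 0)) stop("base weights must be positive",
                                     call. = FALSE)
    base_weights / sum(base_weights)
  }
  targets <- colMeans(Xt)

  # feasibility: each target must lie within the range of the control column
  lo <- apply(Xc, 2, min)
  hi <- apply(Xc, 2, max)
  eps <- 1e-12 + 1e-9 * pmax(abs(lo), abs(hi))
  bad <- which(targets < lo - eps | targets > hi + eps)
  constant <- which(hi - lo <= eps & abs(targets - lo) > eps)
  if (length(bad) || length(constant)) {
    nm <- colnames(Xc)[union(bad, constant)]
    stop("infeasible balance target for moment(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }

  # drop constant columns whose target is already met (no tilt needed)
  keep <- hi - lo > eps
  C <- sweep(Xc[, keep, drop = FALSE], 2, targets[keep])  # centred at target
  p <- ncol(C)
  lambda <- rep(0, p)

  viol_of <- function(lambda) {
    eta <- drop(C %*% lambda)
    eta <- eta - max(eta)  # overflow guard; cancels in the normalization
    v <- q * exp(eta)
    w <- v / sum(v)
    m <- drop(crossprod(C, w))
    list(w = w, gap = m)  # gap = weighted mean minus target
  }

  st <- viol_of(lambda)
  iter <- 0L
  converged <- max(abs(st$gap)) <= tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    Cw <- C * st$w
    H <- crossprod(C, Cw) - tcrossprod(st$gap)  # weighted covariance of C
    step <- tryCatch(solve(H + diag(1e-12, p), -st$gap),
                     error = function(e) -st$gap)
    # step halving on the violation norm
    ok <- FALSE
    for (h in 0:30) {
      cand <- lambda + step / 2^h
      stc <- viol_of(cand)
      if (max(abs(stc$gap)) < max(abs(st$gap))) {
        lambda <- cand
        st <- stc
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    converged <- max(abs(st$gap)) <= tol
  }
  if (!converged) {
    stop(sprintf(
      "entropy balancing did not converge in %d iterations (max violation %.3g)",
      iter, max(abs(st$gap))), call. = FALSE)
  }

  weights <- st$w * n_t  # convention: control weights sum to n treated
  lam_full <- rep(0, ncol(Xc))
  names(lam_full) <- colnames(Xc)
  lam_full[keep] <- lambda
  out <- list(weights = weights, converged = converged, iterations = iter,
              max_violation = max(abs(st$gap)), lambda = lam_full,
              targets = targets, moment_order = moment_order,
              n_treated = n_t)
  class(out) <- "balance_weights"
  out
}

#' @export
print.balance_weights <- function(x, ...) {
  cat(sprintf(
    "Entropy balancing: %d control weights (sum %.1f), %d iterations, max violation %.2g\n",
    length(x$weights), sum(x$weights), x$iterations, x$max_violation))
  invisible(x)
}

#' Covariate balance diagnostics
#'
#' Raw and weighted standardized mean differences between treated and
#' control groups. The standardized difference divides the mean gap by the
#' pooled (unweighted) standard deviation; weighting applies only to the
#' control means, mirroring the reweighting estimators.
#'
#' @param panel Panel data frame with a 0/1 treatment-group column.
#' @param weights Control-unit weights aligned with the control rows of
#'   `panel` in order (e.g. from [entropy_balance()]), or `NULL` for uniform.
#' @param covariates Covariate columns to tabulate.
#' @param treat_col Name of the treatment-group column.
#' @return Data frame with per-covariate treated/control means, raw and
#'   weighted standardized mean differences.
#' @export
balance_table <- function(panel, weights = NULL, covariates,
                          treat_col = "treat") {
  tr <- panel[[treat_col]] == 1
  if (inherits(weights, "balance_weights")) weights <- weights$weights
  if (is.null(weights)) weights <- rep(1, sum(!tr))
  stopifnot(length(weights) == sum(!tr))
  rows <- lapply(covariates, function(cv) {
    xt <- panel[[cv]][tr]
    xc <- panel[[cv]][!tr]
    sd_pool <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
    denom <- if (is.finite(sd_pool) && sd_pool > 0) sd_pool else 1
    data.frame(
      covariate = cv,
      mean_treated = mean(xt),
      mean_control = mean(xc),
      smd_raw = (mean(xt) - mean(xc)) / denom,
      mean_control_weighted = stats::weighted.mean(xc, weights),
      smd_weighted = (mean(xt) - stats::weighted.mean(xc, weights)) / denom
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logistic propensity scores by IRLS
#'
#' Fits a logistic regression of treatment-group membership on covariates by
#' iteratively reweighted least squares and returns the fitted treatment
#' probabilities. Constant covariate columns are dropped with a message;
#' perfect separation (divergent linear predictor) is an error.
#'
#' @param panel Panel data frame.
#' @param covariates Covariate columns.
#' @param treat_col 0/1 treatment-group column.
#' @param max_iter IRLS iteration cap.
#' @param tol Convergence tolerance on the deviance change.
#' @return A `propensity_fit`: `scores` (fitted probabilities),
#'   `coefficients`, `iterations`, `converged`.
#' @export
fit_propensity <- function(panel, covariates, treat_col = "treat",
                           max_iter = 50L, tol = 1e-10) {
  y <- panel[[treat_col]]
  if (is.null(y) || !all(y %in% c(0, 1))) {
    stop("treatment column must be 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("both treatment classes must be present", call. = FALSE)
  }
  X <- as.matrix(panel[covariates])
  constant <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, X)

  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30 && iter > 1L) {
      stop("perfect separation detected in propensity model", call. = FALSE)
    }
    mu <- stats::plogis(eta)
    wirls <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wirls
    fit <- stats::lm.wfit(X, z, wirls)
    beta <- fit$coefficients
    mu_new <- stats::plogis(drop(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                    (1 - y) * log(pmax(1 - mu_new, 1e-300)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  scores <- stats::plogis(drop(X %*% beta))
  names(beta) <- colnames(X)
  out <- list(scores = scores, coefficients = beta, iterations = iter,
              converged = converged)
  class(out) <- "propensity_fit"
  out
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity model (IRLS, %d iterations%s)\n", x$iterations,
              if (x$converged) "" else ", not converged"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Greedy nearest-neighbour caliper matching on the propensity score
#'
#' Matches each treated unit to the nearest control on the logit of the
#' propensity score within `caliper`. Treated units are processed in
#' descending score order, ties broken by unit identifier; without
#' replacement a control is used at most once. Unmatched treated units are
#' reported.
#'
#' @param scores Propensity scores in (0, 1) for all units (named, or
#'   indexed positionally).
#' @param treat 0/1 vector aligned with `scores`.
#' @param caliper Maximum score distance (default 0.05 on the logit scale).
#' @param with_replacement Allow a control to match several treated units.
#' @param distance_scale Match on the logit of the score (default) or on the
#'   raw probability scale.
#' @return A `match_result`: `pairs` data frame (`treated`, `control`,
#'   `distance` on the chosen scale) and `unmatched` treated identifiers.
#' @export
nearest_neighbor_match <- function(scores, treat, caliper = 0.05,
                                   with_replacement = FALSE,
                                   distance_scale = c("logit", "probability")) {
  distance_scale <- match.arg(distance_scale)
  stopifnot(length(scores) == length(treat), all(is.finite(scores)))
  ids <- if (!is.null(names(scores))) names(scores) else
    as.character(seq_along(scores))
  lg <- if (distance_scale == "logit") {
    stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  } else {
    scores
  }
  t_idx <- which(treat == 1)
  c_idx <- which(treat == 0)
  # greedy order: descending treated score, ties by identifier
  t_idx <- t_idx[order(-lg[t_idx], ids[t_idx])]

  pairs <- list()
  unmatched <- character(0)
  used <- logical(length(scores))
  for (ti in t_idx) {
    avail <- if (with_replacement) c_idx else c_idx[!used[c_idx]]
    if (length(avail) == 0L) {
      unmatched <- c(unmatched, ids[ti])
      next
    }
    d <- abs(lg[avail] - lg[ti])
    ord <- order(d, ids[avail])
    best <- avail[ord[1L]]
    if (d[ord[1L]] <= caliper) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        treated = ids[ti], control = ids[best],
        distance = d[ord[1L]], stringsAsFactors = FALSE)
      used[best] <- TRUE
    } else {
      unmatched <- c(unmatched, ids[ti])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated = character(0), control = character(0),
               distance = numeric(0))
  if (length(unmatched)) {
    message(sprintf("%d treated unit(s) unmatched within caliper %.3g",
                    length(unmatched), caliper))
  }
  out <- list(pairs = pairs, unmatched = unmatched, caliper = caliper,
              with_replacement = with_replacement)
  class(out) <- "match_result"
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Nearest-neighbour matching: %d pairs, %d unmatched (caliper %.3g%s)\n",
              nrow(x$pairs), length(x$unmatched), x$caliper,
              if (x$with_replacement) ", with replacement" else ""))
  invisible(x)
}
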