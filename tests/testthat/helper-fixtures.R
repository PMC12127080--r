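# Shared fixtures and independent oracles for the test suite.

FULL_COVARIATES <- c("gender", "age", "bmi", "education", "rural", "sleep",
                     "smoke", "drink", "hypertension", "diabetes")

# small default-structure cohort (125-region calendar scaled down)
small_cfg <- function(..., n_regions = 40, n_individuals_per_region = 30,
                      seed = 1L) {
  args <- list(...)
  if (is.null(args$treated_cohorts) && n_regions < 9) {
    args$treated_cohorts <- data.frame(adoption_year = 2013L,
                                       n_regions = 1L)
  }
  do.call(cohort_config,
          c(list(n_regions = n_regions,
                 n_individuals_per_region = n_individuals_per_region,
                 seed = seed), args))
}

# pseudo-inverse OLS oracle, independent of the QR/Cholesky paths
pinv_coef <- function(X, y, w = rep(1, nrow(X))) {
  Xw <- X * sqrt(w)
  s <- svd(Xw)
  pos <- s$d > max(dim(Xw)) * .Machine$double.eps * s$d[1]
  drop(s$v[, pos, drop = FALSE] %*%
         ((crossprod(s$u[, pos, drop = FALSE], y * sqrt(w))) / s$d[pos]))
}

# hand-built two-period panel with simultaneous adoption for the 2x2 identity
make_2x2_panel <- function(seed = 1, n_per_cell = 60) {
  withr::with_seed(seed, {
    regions <- sprintf("G%02d", 1:10)
    treated <- regions[1:4]
    grid <- expand.grid(region_id = regions,
                        i = seq_len(n_per_cell),
                        wave = c(2011, 2015),
                        stringsAsFactors = FALSE)
    grid$individual_id <- paste0(grid$region_id, "-", grid$i)
    p <- 0.10 +
      0.04 * (grid$region_id %in% treated) +
      0.02 * (grid$wave == 2015) -
      0.05 * (grid$region_id %in% treated & grid$wave == 2015)
    grid$cancer <- 1000 * stats::rbinom(nrow(grid), 1, p)
    schedule <- data.frame(region_id = regions,
                           adoption_year = ifelse(regions %in% treated,
                                                  2015L, NA_integer_))
    list(panel = grid[c("individual_id", "region_id", "wave", "cancer")],
         schedule = schedule)
  })
}

# brute-force primal entropy-balancing oracle: minimize the KL divergence
# over the feasible affine subspace (weights summing to 1, moment
# constraints), parameterized through the null space of the constraints
primal_balance_oracle <- function(control, targets, tol = 1e-12) {
  Xc <- as.matrix(control)
  n <- nrow(Xc)
  A <- rbind(rep(1, n), t(Xc))          # constraints: sum w = 1, X'w = target
  b <- c(1, targets)
  w0 <- drop(qr.solve(A %*% t(A), b))   # a feasible point (min-norm)
  w0 <- drop(t(A) %*% w0)
  NS <- qr.Q(qr(t(A)), complete = TRUE)[, (nrow(A) + 1):n, drop = FALSE]
  kl <- function(theta) {
    w <- w0 + drop(NS %*% theta)
    if (any(w <= 0)) return(1e10 + sum(pmax(-w, 0)))
    sum(w * log(w * n))
  }
  d <- ncol(NS)
  if (d == 1L) {
    opt <- stats::optimize(function(t) kl(t), interval = c(-5, 5),
                           tol = tol)
    theta <- opt$minimum
    obj <- opt$objective
  } else {
    opt <- stats::optim(rep(0, d), kl, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    theta <- opt$par
    obj <- opt$value
  }
  list(weights = w0 + drop(NS %*% theta), objective = obj)
}

# KL divergence of normalized weights from uniform base weights
kl_objective <- function(weights) {
  w <- weights / sum(weights)
  sum(w * log(w * length(w)))
}
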