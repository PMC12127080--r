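# Entropy-weight-method construction of a composite pollution index from
# region-year indicator tables. Indicators with greater dispersion (lower
# Shannon entropy of their normalized shares) receive larger weights.

#' Min--max normalization of indicator columns
#'
#' Normalizes each indicator column to \[0, 1\] over the pooled region-year
#' rows, direction-aware: larger-is-more-polluted columns map as
#' `(x - min) / (max - min)`, inverse-direction columns as
#' `(max - x) / (max - min)`. Constant columns cannot be normalized; they
#' are flagged in attribute `degenerate` and returned as `NA` so the
#' weighting step can exclude them.
#'
#' @param table Indicator table: a data frame whose non-identifier columns
#'   are non-negative numeric indicators.
#' @param indicators Indicator column names (default: every column except
#'   `region_id` and `year`).
#' @param directions Named logical vector, `TRUE` (default for all) meaning
#'   larger values indicate more pollution.
#' @return Numeric matrix of normalized values with attribute `degenerate`
#'   (names of constant columns).
#' @examples
#' tab <- data.frame(a = c(10, 20, 30))
#' normalize_indicators(tab, indicators = "a")  # 0, 0.5, 1
#' @export
normalize_indicators <- function(table, indicators = NULL,
                                 directions = NULL) {
  if (is.null(indicators)) {
    indicators <- setdiff(names(table), c("region_id", "year"))
  }
  if (nrow(table) < 2L) {
    stop("indicator table needs at least 2 rows to normalize", call. = FALSE)
  }
  X <- as.matrix(table[indicators])
  if (any(X < 0, na.rm = TRUE)) {
    stop("raw indicator values must be non-negative", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  degenerate <- character(0)
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    if (rng[2] == rng[1]) {
      degenerate <- c(degenerate, indicators[j])
      next
    }
    up <- if (is.null(directions) || !identical(directions[[indicators[j]]],
                                                FALSE)) TRUE else FALSE
    out[, j] <- if (up) (X[, j] - rng[1]) / (rng[2] - rng[1])
                else (rng[2] - X[, j]) / (rng[2] - rng[1])
  }
  if (length(degenerate)) {
    message("constant indicator column(s) excluded from weighting: ",
            paste(degenerate, collapse = ", "))
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Entropy weights for normalized indicators
#'
#' Computes the classic entropy-weight-method weights: column shares
#' `p_ij = x_ij / sum_i x_ij`, Shannon entropy
#' `e_j = -(1/ln n) sum_i p_ij ln p_ij` (with `0 ln 0 = 0`), divergence
#' `d_j = 1 - e_j`, and weights `w_j = d_j / sum_k d_k`. Uniform columns
#' have maximal entropy and contribute zero weight; degenerate (constant,
#' all-`NA`) columns are excluded.
#'
#' @param normalized Matrix from [normalize_indicators()] (values in
#'   \[0, 1\]).
#' @return Named weight vector over the retained columns, summing to 1,
#'   with attribute `entropy` holding the per-column `e_j`.
#' @export
entropy_weights <- function(normalized) {
  X <- as.matrix(normalized)
  keep <- colSums(is.na(X)) == 0 & colSums(X, na.rm = TRUE) > 0
  if (!any(keep)) {
    stop("all indicator columns are degenerate; no weights computable",
         call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  e <- apply(X, 2, function(col) {
    p <- col / sum(col)
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(n)
  })
  d <- 1 - e
  if (sum(d) <= 0) {
    stop("all retained indicators have maximal entropy; weights undefined",
         call. = FALSE)
  }
  w <- d / sum(d)
  attr(w, "entropy") <- e
  w
}

#' Composite index from normalized indicators and weights
#'
#' `index_i = sum_j w_j x_ij` over the retained (weighted) columns; lies in
#' \[0, 1\] under min--max normalization since the weights sum to 1.
#'
#' @param normalized Matrix from [normalize_indicators()].
#' @param weights Weights from [entropy_weights()].
#' @return Numeric vector, one index value per row.
#' @export
composite_index <- function(normalized, weights) {
  X <- as.matrix(normalized)[, names(weights), drop = FALSE]
  drop(X %*% weights)
}

#' Build the composite pollution index for a region-year table
#'
#' Convenience wrapper: normalize, weight, and join the index back to the
#' `(region_id, year)` keys so it can be merged into a panel as the external
#' moderator.
#'
#' @inheritParams normalize_indicators
#' @return A data frame `region_id, year, pollution_index` with attributes
#'   `weights` and `entropy`.
#' @export
build_pollution_index <- function(table, indicators = NULL,
                                  directions = NULL) {
  stopifnot(all(c("region_id", "year") %in% names(table)))
  if (anyDuplicated(table[c("region_id", "year")])) {
    stop("(region_id, year) keys must be unique", call. = FALSE)
  }
  nz <- normalize_indicators(table, indicators, directions)
  w <- entropy_weights(nz)
  out <- data.frame(region_id = table$region_id, year = table$year,
                    pollution_index = composite_index(nz, w),
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  attr(out, "entropy") <- attr(w, "entropy")
  out
}

#' Merge a pollution index into a panel as a moderator column
#'
#' Joins on `region_id` and `wave == year`.
#'
#' @param panel Panel data frame.
#' @param index Output of [build_pollution_index()].
#' @param name Column name for the merged moderator.
#' @return The panel with the index column added (`NA` where no region-year
#'   match exists).
#' @export
merge_pollution_index <- function(panel, index, name = "pollution_index") {
  key_p <- paste(panel$region_id, panel$wave, sep = "\r")
  key_i <- paste(index$region_id, index$year, sep = "\r")
  panel[[name]] <- index$pollution_index[match(key_p, key_i)]
  if (anyNA(panel[[name]])) {
    message(sprintf("%d panel record(s) have no matching region-year index",
                    sum(is.na(panel[[name]]))))
  }
  panel
}
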