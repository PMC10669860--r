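# Agreement statistics: Spearman rank correlation with 95% CIs and
# Krippendorff's alpha for continuous ratings with missing entries.

#' Average ranks with midranks for ties
#'
#' Tied values receive the mean of the ranks they span, so the ranks always
#' sum to n(n+1)/2.
#'
#' @param values Numeric vector, finite, non-empty.
#' @return Numeric vector of average ranks.
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0L || anyNA(values) || !all(is.finite(values))) {
    abort("rank_with_ties requires non-empty finite values.",
          class = "eruptq_error_stats")
  }
  rank(values, ties.method = "average")
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of the average ranks of `x` and `y` (midranks for
#' ties).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return The correlation `rho` in \[-1, 1\]; `NA` with a warning if either
#'   variable is constant (rho undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("spearman_rho needs equal-length vectors with n >= 3.",
          class = "eruptq_error_stats")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warn("Spearman's rho undefined for a constant variable; returning NA.")
    return(NA_real_)
  }
  cor(rank_with_ties(x), rank_with_ties(y), method = "pearson")
}

#' Confidence interval for Spearman's rho
#'
#' Fisher z-transform interval with the Bonett--Wright standard error
#' `sqrt((1 + rho^2 / 2) / (n - 3))`, back-transformed to the rho scale.
#' Degenerate input `|rho| = 1` yields the flagged point interval
#' `(rho, rho)`.
#'
#' @param rho Estimated Spearman correlation.
#' @param n Number of pairs (n >= 5 for a non-degenerate interval).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `lcl`, `ucl`, `level`, `ci_method`, `degenerate`.
#' @export
spearman_ci <- function(rho, n, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.na(rho)) {
    return(tibble(lcl = NA_real_, ucl = NA_real_, level = level,
                  ci_method = "fisher_bonett_wright", degenerate = TRUE))
  }
  if (abs(rho) >= 1) {
    return(tibble(lcl = rho, ucl = rho, level = level,
                  ci_method = "fisher_bonett_wright", degenerate = TRUE))
  }
  if (n < 5L) {
    abort("spearman_ci requires n >= 5.", class = "eruptq_error_stats")
  }
  z <- atanh(rho)
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  crit <- qnorm(1 - (1 - level) / 2)
  tibble(lcl = tanh(z - crit * se), ucl = tanh(z + crit * se),
         level = level, ci_method = "fisher_bonett_wright",
         degenerate = FALSE)
}

#' Spearman correlation with confidence interval
#'
#' Convenience wrapper combining [spearman_rho()] and a 95% confidence
#' interval, either the analytic Fisher/Bonett--Wright interval or a
#' unit-level percentile bootstrap.
#'
#' @param x,y Numeric vectors of equal length.
#' @param level Confidence level.
#' @param ci_method `"fisher_bw"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (bootstrap method only).
#' @param seed Integer seed (required for the bootstrap method).
#' @return One-row tibble: `rho`, `n`, `lcl`, `ucl`, `level`, `ci_method`,
#'   `degenerate`.
#' @export
spearman_estimate <- function(x, y, level = 0.95,
                              ci_method = c("fisher_bw", "bootstrap"),
                              n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (ci_method == "fisher_bw" || is.na(rho) || abs(rho) >= 1) {
    ci <- spearman_ci(rho, n, level)
  } else {
    if (is.null(seed)) abort("Bootstrap CI requires an explicit seed.",
                             class = "eruptq_error_stats")
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) < 2L || length(unique(y[idx])) < 2L) {
        return(NA_real_)
      }
      cor(rank(x[idx]), rank(y[idx]))
    }, numeric(1))
    boots <- boots[!is.na(boots)]
    if (length(boots) < 20L) {
      abort("Too few valid bootstrap resamples for a Spearman CI.",
            class = "eruptq_error_stats")
    }
    qs <- unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                                 type = 7))
    ci <- tibble(lcl = qs[1], ucl = qs[2], level = level,
                 ci_method = "unit_bootstrap_percentile", degenerate = FALSE)
  }
  tibble(rho = rho, n = n, lcl = ci$lcl, ucl = ci$ucl, level = ci$level,
         ci_method = ci$ci_method, degenerate = ci$degenerate)
}

#' Krippendorff's alpha for continuous ratings
#'
#' Chance-corrected agreement `alpha = 1 - D_o / D_e` for a units x observers
#' matrix of continuous ratings with missing entries permitted. The observed
#' disagreement `D_o` averages the squared difference over all ordered pairs
#' of ratings within each unit (each unit weighted by `m_u - 1`); the
#' expected disagreement `D_e` averages it over all ordered pairs of pooled
#' pairable ratings. Units with fewer than two non-missing ratings cannot
#' contribute pairs and are dropped (and counted) before estimation.
#'
#' Difference functions: `interval` uses `(c - k)^2` (invariant under affine
#' rescaling of all ratings); `ratio` uses `((c - k) / (c + k))^2` (invariant
#' under positive scaling; requires `c + k != 0`).
#'
#' @param values A numeric matrix, units in rows, observers in columns, `NA`
#'   for missing; or a data frame of the same shape.
#' @param metric `"interval"` (default) or `"ratio"`.
#' @return Alpha as a double (<= 1), with attributes `n_units` (units kept),
#'   `n_dropped` (units dropped for having < 2 ratings), `n_pairable` (total
#'   pairable ratings) and `metric`. `NA` with a warning when `D_e = 0` (all
#'   pooled ratings identical).
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 1), r2 = c(1, 2, 3, 3))
#' krippendorff_alpha(m) # 0.41667
krippendorff_alpha <- function(values, metric = c("interval", "ratio")) {
  metric <- match.arg(metric)
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) {
    abort("Krippendorff's alpha needs at least 2 observers.",
          class = "eruptq_error_stats")
  }
  m_u <- rowSums(!is.na(m))
  keep <- m_u >= 2L
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  m_u <- m_u[keep]
  if (nrow(m) < 2L) {
    abort("Fewer than 2 pairable units after dropping units with < 2 ratings.",
          class = "eruptq_error_stats")
  }
  pooled <- m[!is.na(m)]
  n <- length(pooled)

  delta2_sum <- function(v) {
    # sum of (c - k)^2, resp. ((c - k)/(c + k))^2, over ordered pairs
    if (metric == "interval") {
      k <- length(v)
      2 * (k * sum(v^2) - sum(v)^2)
    } else {
      if (any(outer(v, v, "+") == 0 & outer(v, v, "-") != 0)) {
        abort("Ratio metric undefined: pair with c + k = 0.",
              class = "eruptq_error_stats")
      }
      d <- outer(v, v, "-") / outer(v, v, "+")
      d[is.nan(d)] <- 0 # 0/0 pairs: identical zero ratings, no disagreement
      sum(d^2)
    }
  }

  d_o <- sum(vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    delta2_sum(v[!is.na(v)]) / (m_u[i] - 1)
  }, numeric(1))) / n
  d_e <- delta2_sum(pooled) / (n * (n - 1))

  if (d_e == 0) {
    warn("Krippendorff's alpha undefined: all pooled ratings identical (D_e = 0).")
    alpha <- NA_real_
  } else {
    alpha <- 1 - d_o / d_e
  }
  structure(alpha, n_units = nrow(m), n_dropped = n_dropped,
            n_pairable = n, metric = metric)
}

#' Bootstrap confidence interval for Krippendorff's alpha
#'
#' Percentile interval from a cluster bootstrap that resamples units
#' (rows) with replacement, keeping each unit's ratings together. Resamples
#' on which alpha is undefined are redrawn, up to 10 x `n_boot` attempts.
#' Deterministic given `seed`.
#'
#' @inheritParams krippendorff_alpha
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (required; no hidden global state).
#' @return One-row tibble: `lcl`, `ucl`, `level`, `n_boot`, `n_invalid`
#'   (resamples discarded as undefined), `seed`.
#' @export
alpha_bootstrap_ci <- function(values, metric = c("interval", "ratio"),
                               n_boot = 2000L, level = 0.95, seed) {
  metric <- match.arg(metric)
  if (missing(seed) || is.null(seed)) {
    abort("alpha_bootstrap_ci requires an explicit seed.",
          class = "eruptq_error_stats")
  }
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  keep <- rowSums(!is.na(m)) >= 2L
  m <- m[keep, , drop = FALSE]
  point <- krippendorff_alpha(m, metric) # validates; errors propagate
  n_units <- nrow(m)
  set.seed(as.integer(seed))
  alphas <- numeric(0)
  n_invalid <- 0L
  attempts <- 0L
  max_attempts <- 10L * n_boot
  while (length(alphas) < n_boot && attempts < max_attempts) {
    todo <- n_boot - length(alphas)
    draws <- vapply(seq_len(todo), function(i) {
      idx <- sample.int(n_units, n_units, replace = TRUE)
      suppressWarnings(
        tryCatch(as.numeric(krippendorff_alpha(m[idx, , drop = FALSE], metric)),
                 error = function(e) NA_real_)
      )
    }, numeric(1))
    n_invalid <- n_invalid + sum(is.na(draws))
    alphas <- c(alphas, draws[!is.na(draws)])
    attempts <- attempts + todo
  }
  if (length(alphas) < 20L) {
    abort("Fewer than 20 valid bootstrap resamples; alpha CI not estimable.",
          class = "eruptq_error_stats")
  }
  alphas <- alphas[seq_len(min(length(alphas), n_boot))]
  qs <- unname(stats::quantile(alphas, c((1 - level) / 2, 1 - (1 - level) / 2),
                               type = 7))
  tibble(lcl = qs[1], ucl = qs[2], level = level,
         n_boot = length(alphas), n_invalid = n_invalid,
         seed = as.integer(seed))
}

#' Reliability estimate (alpha with bootstrap CI)
#'
#' @inheritParams alpha_bootstrap_ci
#' @return One-row tibble: `alpha`, `metric`, `n_units`, `n_dropped`,
#'   `n_pairable`, `lcl`, `ucl`, `level`, `n_boot`, `seed`.
#' @export
reliability_estimate <- function(values, metric = c("interval", "ratio"),
                                 n_boot = 2000L, level = 0.95, seed) {
  metric <- match.arg(metric)
  a <- krippendorff_alpha(values, metric)
  ci <- alpha_bootstrap_ci(values, metric, n_boot = n_boot, level = level,
                           seed = seed)
  tibble(alpha = as.numeric(a), metric = metric,
         n_units = attr(a, "n_units"), n_dropped = attr(a, "n_dropped"),
         n_pairable = attr(a, "n_pairable"),
         lcl = ci$lcl, ucl = ci$ucl, level = level,
         n_boot = ci$n_boot, seed = ci$seed)
}

#' Read / write a wide ratings matrix
#'
#' Wide CSV serialization: first column `unit`, one column per observer,
#' empty cells for missing ratings.
#'
#' @param path File path.
#' @return `read_ratings`: a numeric matrix with unit rownames and observer
#'   colnames.
#' @export
read_ratings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "unit") {
    abort("Ratings CSV must have `unit` as its first column.",
          class = "eruptq_error_schema")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$unit)
  m
}

#' @rdname read_ratings
#' @param values Numeric matrix, units in rows (rownames used as unit ids).
#' @export
write_ratings <- function(values, path) {
  m <- as.matrix(values)
  df <- as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(
    tibble(unit = rownames(m) %||% as.character(seq_len(nrow(m)))), df
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
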