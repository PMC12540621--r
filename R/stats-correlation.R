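#' Spearman rank correlation
#'
#' The Pearson correlation of average ranks (midranks for ties). Thin,
#' validated front end over the standard routine; undefined for constant
#' input, which is signalled rather than returned as `NA`.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman_r: need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("spearman_r: correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

new_correlation_result <- function(r_values, n_sampled) {
  r_values <- as.numeric(r_values)
  ci <- stats::quantile(r_values, c(0.025, 0.975), names = FALSE)
  structure(list(median_r = stats::median(r_values),
                 ci_low = ci[1], ci_high = ci[2],
                 empirical_p = NA_real_,
                 n_iterations = length(r_values),
                 n = n_sampled,
                 r_values = r_values),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap correlation: median r = %.3f, 95%% CI [%.3f, %.3f] (%d iterations, n = %d)\n",
    x$median_r, x$ci_low, x$ci_high, x$n_iterations, x$n))
  if (!is.na(x$empirical_p)) {
    cat(sprintf("  empirical p vs shuffled null: %s\n",
                format.pval(x$empirical_p, digits = 3)))
  }
  invisible(x)
}

# per-iteration row selection: one measurement per unique participant,
# vectorised across all iterations
sample_one_per_participant <- function(participant_id, n_iter) {
  ord <- order(participant_id)
  pid <- participant_id[ord]
  counts <- as.integer(table(factor(pid, levels = unique(pid))))
  starts <- cumsum(c(0L, counts[-length(counts)]))  # 0-based group offsets
  p <- length(counts)
  u <- stats::runif(p * n_iter)
  offsets <- floor(u * rep(counts, times = n_iter))
  chosen <- rep(starts, times = n_iter) + offsets + 1L
  matrix(ord[chosen], nrow = p, ncol = n_iter)
}

#' Bootstrap Spearman correlation between age and a measure
#'
#' For a mixed longitudinal/cross-sectional design where participants
#' contribute one or more measurements: in each of `n_iter` iterations, one
#' measurement is sampled uniformly per unique participant (so no
#' participant is double counted while the full age range stays covered) and
#' the Spearman correlation between age and the measure is computed. The
#' bootstrap distribution is summarised by its median and 2.5/97.5
#' percentiles.
#'
#' @param measurements Data.frame with `participant_id`, `age_months`, and
#'   the measure column; incomplete rows are dropped.
#' @param value_col Name of the measure column (default `"value"`).
#' @param n_iter Number of bootstrap iterations (default 5000).
#' @param seed Optional integer seed; same seed, same result.
#' @return A `correlation_result`: `median_r`, `ci_low`, `ci_high`,
#'   `empirical_p` (`NA` until paired with a null via [compare_to_null()]),
#'   `n_iterations`, `n` (unique participants per iteration), `r_values`.
#' @export
bootstrap_age_correlation <- function(measurements, value_col = "value",
                                      n_iter = 5000, seed = NULL) {
  boot_corr_impl(measurements, value_col, n_iter, seed, shuffle = FALSE)
}

#' Shuffled-age null distribution for the bootstrap correlation
#'
#' Identical to [bootstrap_age_correlation()] except that, within each
#' iteration, the ages of the sampled records are randomly permuted before
#' computing the correlation — the per-iteration sample size and the
#' marginal distributions are exactly those of the observed bootstrap, but
#' any age-measure association is destroyed.
#'
#' @inheritParams bootstrap_age_correlation
#' @return A `correlation_result`.
#' @export
shuffled_null_correlation <- function(measurements, value_col = "value",
                                      n_iter = 5000, seed = NULL) {
  boot_corr_impl(measurements, value_col, n_iter, seed, shuffle = TRUE)
}

boot_corr_impl <- function(measurements, value_col, n_iter, seed, shuffle) {
  stopifnot(is.data.frame(measurements),
            all(c("participant_id", "age_months", value_col) %in%
                  names(measurements)))
  if (n_iter < 1L) stop("n_iter must be >= 1")
  ok <- stats::complete.cases(measurements$age_months,
                              measurements[[value_col]])
  m <- measurements[ok, ]
  if (length(unique(m$participant_id)) < 3L) {
    stop("need at least 3 unique participants with complete measurements")
  }
  if (length(unique(m[[value_col]])) < 2L) {
    stop("all measurement values identical; correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  age <- m$age_months
  val <- m[[value_col]]
  idx <- sample_one_per_participant(m$participant_id, n_iter)
  p <- nrow(idx)
  r_values <- vapply(seq_len(n_iter), function(i) {
    rows <- idx[, i]
    a <- age[rows]
    if (shuffle) a <- a[sample.int(p)]
    stats::cor(a, val[rows], method = "spearman")
  }, numeric(1))
  new_correlation_result(r_values, p)
}

#' Attach an empirical p value from a shuffled null
#'
#' The empirical p of an observed bootstrap result is the fraction of null
#' iterations whose `|r|` reaches `|median r observed|`, with the standard
#' `(k + 1) / (n + 1)` correction so it is never exactly zero (reported as
#' below `1/n_iter` when no null iteration reaches it). A two-sample
#' Wilcoxon rank-sum comparison between the observed and null r
#' distributions is attached for parity.
#'
#' @param observed,null `correlation_result` objects from
#'   [bootstrap_age_correlation()] and [shuffled_null_correlation()].
#' @return `observed` with `empirical_p` set and a `rank_sum_p` field added.
#' @export
compare_to_null <- function(observed, null) {
  stopifnot(inherits(observed, "correlation_result"),
            inherits(null, "correlation_result"))
  k <- sum(abs(null$r_values) >= abs(observed$median_r))
  observed$empirical_p <- (k + 1) / (null$n_iterations + 1)
  observed$rank_sum_p <- suppressWarnings(
    stats::wilcox.test(observed$r_values, null$r_values)$p.value)
  observed
}
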