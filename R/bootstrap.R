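#' Observed test statistic: absolute difference in group means
#'
#' The statistic on which the bootstrap hypothesis test operates: the
#' absolute difference between the two sample means, in endpoint units.
#'
#' @param group_a,group_b Numeric vectors of endpoint values, one per animal.
#' @return A single non-negative number, `|mean(group_a) - mean(group_b)|`.
#' @examples
#' observed_stat(c(1, 2, 3), c(4, 5, 6)) # 3
#' @export
observed_stat <- function(group_a, group_b) {
  check_sample(group_a, "group_a", min_n = 1)
  check_sample(group_b, "group_b", min_n = 1)
  abs(mean(group_a) - mean(group_b))
}

check_sample <- function(x, name, min_n) {
  if (!is.numeric(x) || length(x) < min_n) {
    stop(sprintf("`%s` must be a numeric vector with at least %d value%s",
                 name, min_n, if (min_n > 1) "s" else ""), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

#' Bootstrap p-value from a vector of resampled statistics
#'
#' Counts the resampled test statistics that are greater than or equal to the
#' observed statistic and divides by their number. The comparison is
#' inclusive (`>=`) and no +1 smoothing is applied, so the minimum attainable
#' p-value is 0. For example, if 2,500 of 10,000 resampled statistics are at
#' least as large as the observed absolute difference in means, the p-value
#' is 0.25: under no true group difference, a statistic that extreme would
#' arise by chance 25% of the time.
#'
#' @param stats Numeric vector of bootstrap test statistics.
#' @param observed The observed test statistic (see [observed_stat()]).
#' @return The fraction of `stats` that are `>= observed`, in \[0, 1\].
#' @export
bootstrap_pvalue <- function(stats, observed) {
  check_sample(stats, "stats", min_n = 1)
  stop_if_not_scalar_number(observed, "observed")
  sum(stats >= observed) / length(stats)
}

#' Bootstrap hypothesis test for the absolute difference in group means
#'
#' Resampling alternative to the two-sample t-test, intended for the small
#' group sizes typical of preclinical colitis studies. The observed statistic
#' is `|mean(a) - mean(b)|`. Under the default `"pooled"` strategy the two
#' samples are combined and each bootstrap iteration draws, with replacement
#' from the pooled values, one resample of size `length(group_a)` and one of
#' size `length(group_b)`; pooling imposes the null hypothesis of no group
#' difference, so the resampling distribution is a genuine null reference.
#' The `"per-group"` strategy resamples each group from itself instead and is
#' provided for comparison with pipelines that resample that way. The p-value
#' is the inclusive fraction of resampled statistics at or above the observed
#' one ([bootstrap_pvalue()]).
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @param n_iterations Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   result. `NULL` uses the current RNG stream.
#' @param strategy `"pooled"` (default, null-imposing) or `"per-group"`.
#' @return A `bootstrap_result` object: a list with `observed_test_stat`,
#'   `p_bootstrap`, `n_iterations`, `seed`, `strategy`, and
#'   `bootstrap_stats_summary` (quantiles of the resampled statistics).
#' @examples
#' res <- bootstrap_p(c(9.1, 8.7, 9.4), c(8.9, 9.0, 9.2), seed = 1)
#' res$p_bootstrap
#' @export
bootstrap_p <- function(group_a, group_b, n_iterations = 10000, seed = NULL,
                        strategy = c("pooled", "per-group")) {
  strategy <- match.arg(strategy)
  check_sample(group_a, "group_a", min_n = 2)
  check_sample(group_b, "group_b", min_n = 2)
  stop_if_not_scalar_number(n_iterations, "n_iterations", min = 1)
  n_iterations <- as.integer(n_iterations)

  obs <- observed_stat(group_a, group_b)
  na <- length(group_a)
  nb <- length(group_b)

  stats <- with_seed(seed, {
    if (strategy == "pooled") {
      pool <- c(group_a, group_b)
      ma <- colMeans(matrix(sample(pool, na * n_iterations, replace = TRUE),
                            nrow = na))
      mb <- colMeans(matrix(sample(pool, nb * n_iterations, replace = TRUE),
                            nrow = nb))
    } else {
      ma <- colMeans(matrix(sample(group_a, na * n_iterations, replace = TRUE),
                            nrow = na))
      mb <- colMeans(matrix(sample(group_b, nb * n_iterations, replace = TRUE),
                            nrow = nb))
    }
    abs(ma - mb)
  })

  structure(
    list(
      observed_test_stat = obs,
      p_bootstrap = bootstrap_pvalue(stats, obs),
      n_iterations = n_iterations,
      seed = seed,
      strategy = strategy,
      bootstrap_stats_summary = stats::quantile(
        stats, c(0, 0.25, 0.5, 0.75, 0.95, 1))
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap hypothesis test (", x$strategy, " resampling)\n", sep = "")
  cat(sprintf("  observed |difference in means| : %.4f\n",
              x$observed_test_stat))
  cat(sprintf("  P_bootstrap                    : %.4f  (%d iterations)\n",
              x$p_bootstrap, x$n_iterations))
  invisible(x)
}

#' Exact enumeration oracle for the pooled bootstrap p-value
#'
#' Enumerates every equally likely with-replacement resample pair under
#' pooled-null resampling and returns the exact probability that the
#' resampled absolute difference in means is at least the observed one. With
#' pool size `N = length(a) + length(b)` there are `N^N` outcomes, so this is
#' feasible only for very small groups; it exists as ground truth against
#' which the Monte-Carlo [bootstrap_p()] is verified.
#'
#' @inheritParams bootstrap_p
#' @param max_outcomes Refuse instances with more than this many enumerated
#'   outcomes (default 1e7).
#' @return The exact p-value as a single number in \[0, 1\].
#' @examples
#' exact_p_oracle(c(1, 1), c(2, 2)) # 0.125
#' @export
exact_p_oracle <- function(group_a, group_b, max_outcomes = 1e7) {
  check_sample(group_a, "group_a", min_n = 1)
  check_sample(group_b, "group_b", min_n = 1)
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb
  if (n^n > max_outcomes) {
    stop(sprintf(
      "instance too large: %d^%d = %.3g enumerated outcomes exceeds the %g bound",
      n, n, n^n, max_outcomes), call. = FALSE)
  }
  obs <- observed_stat(group_a, group_b)
  pool <- c(group_a, group_b)
  means_a <- enumerate_resample_means(pool, na)
  means_b <- enumerate_resample_means(pool, nb)
  # All (a-resample, b-resample) pairs are equally likely and independent.
  mean(outer(means_a, means_b, function(x, y) abs(x - y) >= obs))
}

# Means of all N^k with-replacement resamples of size k from `pool`,
# in enumeration order (each equally likely).
enumerate_resample_means <- function(pool, k) {
  idx <- as.matrix(expand.grid(rep(list(seq_along(pool)), k)))
  rowSums(matrix(pool[idx], ncol = k)) / k
}
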