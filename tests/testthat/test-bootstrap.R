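test_that("observed statistic is the absolute difference in means", {
  expect_equal(observed_stat(c(1, 2, 3), c(4, 5, 6)), 3)
  expect_equal(observed_stat(c(2, 2), c(2, 2)), 0)
  # a reported-style contrast: shifting one group by 0.2670 reproduces the
  # difference exactly
  a <- c(8.1, 9.3, 7.7, 8.8)
  expect_equal(observed_stat(a, a + 0.2670), 0.2670)
  expect_error(observed_stat(numeric(0), 1), "at least 1")
  expect_error(observed_stat(c(1, NA), c(1, 2)), "non-finite")
})

test_that("p-value counting is the inclusive fraction at or above observed", {
  stats <- c(rep(12, 7500), rep(14, 2500))
  expect_identical(bootstrap_pvalue(stats, 13), 0.25)
  # ties count: statistics equal to the observed value qualify
  expect_identical(bootstrap_pvalue(c(13, 12, 14, 13), 13), 0.75)
  # no smoothing: p can reach 0
  expect_identical(bootstrap_pvalue(rep(1, 100), 2), 0)
})

test_that("degenerate identical groups give observed 0 and p 1", {
  for (c0 in c(-3.2, 0, 7)) {
    res <- bootstrap_p(rep(c0, 3), rep(c0, 3), n_iterations = 500, seed = 1)
    expect_identical(res$observed_test_stat, 0)
    expect_identical(res$p_bootstrap, 1)
  }
  # per-group resampling of constants is equally degenerate
  res <- bootstrap_p(rep(2, 3), rep(2, 3), n_iterations = 500, seed = 1,
                     strategy = "per-group")
  expect_identical(res$p_bootstrap, 1)
})

test_that("bootstrap test is deterministic given a seed and leaves the RNG alone", {
  a <- rnorm(8)
  b <- rnorm(8)
  r1 <- bootstrap_p(a, b, seed = 42)
  r2 <- bootstrap_p(a, b, seed = 42)
  expect_identical(r1$p_bootstrap, r2$p_bootstrap)
  expect_identical(r1$bootstrap_stats_summary, r2$bootstrap_stats_summary)
  set.seed(99)
  before <- .Random.seed
  invisible(bootstrap_p(a, b, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("input contracts are enforced", {
  expect_error(bootstrap_p(1, c(1, 2)), "at least 2")
  expect_error(bootstrap_p(c(1, Inf), c(1, 2)), "non-finite")
  expect_error(bootstrap_p(c(1, 2), c(3, 4), n_iterations = 0), ">= 1")
})

test_that("exact oracle matches hand-computed small cases", {
  # pool (1,1,2,2): |mean difference| >= 1 requires one resample all-1s and
  # the other all-2s; 2 * (1/4) * (1/4) = 0.125 over the 256 outcomes
  expect_equal(exact_p_oracle(c(1, 1), c(2, 2)), 0.125)
  expect_equal(exact_p_oracle(c(5, 5), c(5, 5)), 1)
  # observed 0: every outcome qualifies
  expect_equal(exact_p_oracle(c(0, 10), c(0, 10)), 1)
  expect_error(exact_p_oracle(1:4, 1:4), "too large")
})

test_that("oracle agrees with an independent distribution-based computation", {
  # independent route: distribution of a resample mean via table() of all
  # tuples is replaced by the exact multinomial over pool values
  a <- c(0, 1)
  b <- c(2, 3)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  grid <- expand.grid(i = pool, j = pool, k = pool, l = pool)
  p_direct <- mean(abs((grid$i + grid$j) / 2 - (grid$k + grid$l) / 2) >= obs)
  expect_equal(exact_p_oracle(a, b), p_direct)
})

test_that("Monte-Carlo p converges to the exact oracle on small instances", {
  set.seed(2024)
  for (rep in 1:20) {
    na <- sample(2:3, 1)
    nb <- sample(2:3, 1)
    a <- sample(0:5, na, replace = TRUE)
    b <- sample(0:5, nb, replace = TRUE)
    p_exact <- exact_p_oracle(a, b)
    p_mc <- bootstrap_p(a, b, n_iterations = 10000, seed = rep)$p_bootstrap
    band <- 4 * sqrt(p_exact * (1 - p_exact) / 10000)
    expect_lte(abs(p_mc - p_exact), max(band, 1e-12))
  }
})

test_that("p-values are valid probabilities over random instances", {
  set.seed(11)
  for (rep in 1:25) {
    a <- rnorm(sample(2:10, 1), sd = runif(1, 0.1, 5))
    b <- rnorm(sample(2:10, 1), mean = runif(1, -2, 2))
    for (strat in c("pooled", "per-group")) {
      res <- bootstrap_p(a, b, n_iterations = 200, seed = rep,
                         strategy = strat)
      expect_gte(res$p_bootstrap, 0)
      expect_lte(res$p_bootstrap, 1)
      expect_gte(res$observed_test_stat, 0)
    }
  }
})

test_that("median power never decreases along an effect grid", {
  set.seed(404)
  median_p <- vapply(c(0, 1, 2), function(effect) {
    ps <- replicate(100, {
      bootstrap_p(rnorm(8), rnorm(8, mean = effect), n_iterations = 500,
                  seed = sample.int(1e8, 1))$p_bootstrap
    })
    median(ps)
  }, numeric(1))
  expect_true(all(diff(median_p) <= 0))
})
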