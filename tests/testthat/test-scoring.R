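test_that("percent-change bins follow the published rule table", {
  # (value, control, expected points)
  cases <- list(
    list(10, 10, 0L),     # 0% change
    list(9.6, 10, 0L),    # 4%
    list(9.5, 10, 0L),    # exactly 5% stays in the 0-point bin
    list(9.4, 10, 1L),    # 6%
    list(8.6, 10, 1L),    # 14%
    list(8.5, 10, 2L),    # exactly 15% enters the 2-point bin
    list(8, 10, 2L),      # 20%
    list(7.5, 10, 3L),    # exactly 25%
    list(6.6, 10, 3L),    # 34%
    list(6.5, 10, 4L),    # exactly 35%: the severe bin wins
    list(6, 10, 4L),      # 40%
    list(14, 10, 4L)      # deviation is absolute: +40% also scores 4
  )
  for (cs in cases) {
    expect_identical(percent_change_points(cs[[1]], cs[[2]]), cs[[3]])
  }
  expect_error(percent_change_points(5, 0), "> 0")
  expect_error(percent_change_points(-1, 10), ">= 0")
})

test_that("percent-change points are scale invariant", {
  set.seed(5)
  for (i in 1:50) {
    value <- runif(1, 0, 20)
    ctrl <- runif(1, 1, 20)
    k <- runif(1, 0.01, 100)
    expect_identical(percent_change_points(value, ctrl),
                     percent_change_points(k * value, k * ctrl))
  }
})

test_that("macroscopic total sums its components over the 0-15 range", {
  ref <- control_reference(10, 0.25)
  normal <- list(stool_score = 0, ulcer_score = 0, colon_length = 10,
                 colon_weight = 0.25, fecal_blood = 0)
  expect_identical(macroscopic_total(normal, ref)$total, 0L)

  worst <- list(stool_score = 3, ulcer_score = 3, colon_length = 6,
                colon_weight = 0.4, fecal_blood = 1)
  expect_identical(macroscopic_total(worst, ref)$total, 15L)

  mixed <- list(stool_score = 3, ulcer_score = 2, colon_length = 8,
                colon_weight = 0.275, fecal_blood = 1)  # 20% and 10% changes
  res <- macroscopic_total(mixed, ref)
  expect_identical(res$length_points, 2L)
  expect_identical(res$weight_points, 1L)
  expect_identical(res$total, 3L + 2L + 2L + 1L + 1L)
  expect_identical(res$total,
                   res$stool_points + res$ulcer_points + res$length_points +
                     res$weight_points + res$blood_points)
})

test_that("ulcer counts above 3 clamp to the score ceiling", {
  ref <- control_reference(10, 0.25)
  rec <- list(stool_score = 0, ulcer_score = 7, colon_length = 10,
              colon_weight = 0.25, fecal_blood = 0)
  expect_identical(macroscopic_total(rec, ref)$ulcer_points, 3L)
})

test_that("out-of-range ordinal inputs are rejected with the field named", {
  ref <- control_reference(10, 0.25)
  rec <- list(stool_score = 4, ulcer_score = 0, colon_length = 10,
              colon_weight = 0.25, fecal_blood = 0)
  expect_error(macroscopic_total(rec, ref), "stool_score")
  rec$stool_score <- 0
  rec$fecal_blood <- 2
  expect_error(macroscopic_total(rec, ref), "fecal_blood")
  expect_error(microscopic_total(2, 0, 1, 1, 1), "goblet_depletion")
  expect_error(microscopic_total(0, 0, 0, 1, 1), "mucosal_architecture")
})

test_that("microscopic total spans 3-11 and sums subscores", {
  expect_identical(microscopic_total(0, 0, 1, 1, 1), 3L)
  expect_identical(microscopic_total(1, 1, 3, 3, 3), 11L)
  expect_identical(microscopic_total(1, 0, 2, 1, 2), 6L)
})

test_that("totals never decrease when any single input worsens", {
  ref <- control_reference(10, 0.25)
  set.seed(17)
  for (i in 1:40) {
    rec <- list(stool_score = sample(0:3, 1), ulcer_score = sample(0:3, 1),
                colon_length = runif(1, 5, 12),
                colon_weight = runif(1, 0.15, 0.4),
                fecal_blood = sample(0:1, 1))
    base <- macroscopic_total(rec, ref)$total
    expect_gte(base, 0L)
    expect_lte(base, 15L)
    if (rec$stool_score < 3) {
      worse <- rec; worse$stool_score <- worse$stool_score + 1
      expect_gte(macroscopic_total(worse, ref)$total, base)
    }
    if (rec$fecal_blood == 0) {
      worse <- rec; worse$fecal_blood <- 1
      expect_gte(macroscopic_total(worse, ref)$total, base)
    }
    # push the length further from the control mean
    worse <- rec
    worse$colon_length <- 10 + 1.5 * (worse$colon_length - 10)
    expect_gte(macroscopic_total(worse, ref)$total, base)
  }
})

test_that("score_cohort derives the control reference and appends scores", {
  cohort <- generate_cohort(default_design(n_per_group = 5), seed = 3)
  scored <- score_cohort(cohort)
  expect_true(all(scored$macroscopic_score >= 0 &
                    scored$macroscopic_score <= 15))
  expect_true(all(scored$microscopic_score >= 3 &
                    scored$microscopic_score <= 11))
  # explicit reference equal to the derived one gives identical scores
  ctrl <- cohort[cohort$group == "control", ]
  ref <- control_reference(mean(ctrl$colon_length), mean(ctrl$colon_weight))
  expect_identical(score_cohort(cohort, ref)$macroscopic_score,
                   scored$macroscopic_score)
  expect_error(score_cohort(cohort[cohort$group != "control", ]),
               "control")
})
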