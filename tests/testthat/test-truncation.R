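test_that("truncation cuts in the ramp and splices a matching recovery", {
  cohort <- make_maximal_cohort(1, seed = 51, noise = FALSE)
  rec <- cohort[[1]]
  tp71 <- truncate_at_fraction(rec$hr, rec$vo2, rec$protocol,
                               rec$hrmax_measured, 0.71)
  tp95 <- truncate_at_fraction(rec$hr, rec$vo2, rec$protocol,
                               rec$hrmax_measured, 0.95)
  expect_gt(tp95$t_cut, tp71$t_cut)            # monotone crossing times
  expect_equal(tp71$hr$phase[tp71$hr$time_s == tp71$t_cut], "ramp")
  # splice continuity: first recovery sample within one step of the cut value
  for (tp in list(tp71, tp95)) {
    i_cut <- which(tp$hr$time_s == tp$t_cut)
    gap <- tp$hr$value[i_cut] - tp$hr$value[i_cut + 1L]
    expect_gte(gap, 0)                          # forward scan: value <= cut
    step <- max(abs(diff(rec$hr$value[rec$hr$phase == "recovery"])))
    expect_lte(gap, max(step, abs(diff(range(rec$hr$value))) * 0.02))
  }
  # splice conservation: every spliced value exists in the original record
  expect_true(all(tp71$hr$value %in% rec$hr$value))
  expect_true(all(tp71$vo2$value %in% rec$vo2$value))
  # times remain contiguous at 1 Hz
  expect_equal(diff(tp71$hr$time_s), rep(1, nrow(tp71$hr) - 1))
  # a fraction crossed before the ramp is rejected
  expect_error(truncate_at_fraction(rec$hr, rec$vo2, rec$protocol,
                                    rec$hrmax_measured, 0.45),
               "phase|attained")
  expect_error(truncate_at_fraction(rec$hr, rec$vo2, rec$protocol,
                                    rec$hrmax_measured, 1.2), "fraction")
})

test_that("noise-free model cohort predicts VO2max independent of fraction", {
  cohort <- make_maximal_cohort(2, seed = 61, noise = FALSE)
  st <- run_truncation_study(cohort, fractions = c(0.72, 0.80, 0.90))
  expect_true(all(st$table$mean_delta < 0.5))
  expect_lt(diff(range(st$table$mean_delta)), 0.5)
  expect_equal(st$failures, 0)
})

test_that("noisy cohort shows decreasing error with later truncation", {
  cohort <- make_maximal_cohort(5, seed = 71)
  st <- run_truncation_study(cohort,
                             fractions = seq(0.71, 0.95, by = 0.03))
  expect_lt(st$correlation$pearson, 0)
  expect_lt(st$fit$slope, 0)
  f <- st$table$fraction
  expect_lte(st$table$mean_delta[which.min(abs(f - 0.80))],
             st$table$mean_delta[which.min(abs(f - 0.71))])
})

test_that("single-fraction studies skip the regression", {
  cohort <- make_maximal_cohort(2, seed = 81, noise = FALSE)
  st <- run_truncation_study(cohort, fractions = 0.80)
  expect_null(st$fit)
  expect_null(st$correlation)
  expect_equal(nrow(st$table), 1)
})

test_that("termination recommendation scans the mean-error curve", {
  mk <- function(fraction, mean_delta)
    structure(list(table = data.frame(fraction = fraction,
                                      mean_delta = mean_delta)),
              class = "truncation_study")
  # all below threshold -> smallest fraction
  expect_equal(recommend_termination(mk(c(0.71, 0.80, 0.90), c(3, 2, 1)), 6),
               0.71)
  # strictly decreasing curve crossing the threshold -> crossing fraction
  expect_equal(recommend_termination(mk(seq(0.71, 0.75, 0.01),
                                        c(9, 8, 7, 5.5, 4)), 6), 0.74)
  # impossible threshold -> largest fraction with a warning
  expect_warning(r <- recommend_termination(mk(c(0.71, 0.95), c(4, 2)), 0),
                 "threshold")
  expect_equal(r, 0.95)
})
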