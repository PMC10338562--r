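test_that("extrapolation crossing matches a dense-grid oracle within 1 s", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  fit <- fit_kinetics(ser, prot)
  rs <- ramp_span(prot)
  x_start <- ser$value[ser$time_s == rs$end]
  ext <- extrapolate_to_hrmax(fit, prot, hrmax_target = 190,
                              x_start = x_start, t_start = rs$end)
  expect_true(ext$reached)
  # dense 0.01-s brute-force simulation as crossing oracle
  dense_t <- seq(rs$end, ext$t_hrmax_model + 5, by = 0.01)
  dense <- simulate_kinetics(fit$params, extend_ramp(prot),
                             x_start = x_start, times = dense_t)
  t_oracle <- dense_t[which(dense$value >= 190 - 0.1)[1]]
  expect_lt(abs(ext$t_hrmax_model - t_oracle), 1 + 1e-9)
  # 0.1-bpm stopping contract: value at the crossing is within the band
  v_cross <- ext$values[length(ext$values)]
  expect_gte(v_cross, 190 - 0.1)
  step_gain <- fit$params$K * 25   # one staircase step of headroom plus slack
  expect_lte(v_cross, 190 + step_gain + 0.5)
})

test_that("extrapolation handles immediate and unreachable targets", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  fit <- fit_kinetics(ser, prot)
  rs <- ramp_span(prot)
  x_start <- ser$value[ser$time_s == rs$end]
  # target below current HR -> immediate crossing at t_start
  ext0 <- extrapolate_to_hrmax(fit, prot, hrmax_target = x_start - 5,
                               x_start = x_start, t_start = rs$end)
  expect_equal(ext0$t_hrmax_model, rs$end)
  # tiny horizon -> reported unreached, no error
  ext1 <- extrapolate_to_hrmax(fit, prot, hrmax_target = 1000,
                               x_start = x_start, t_start = rs$end,
                               max_horizon_s = 60)
  expect_false(ext1$reached)
  expect_true(is.na(ext1$t_hrmax_model))
  # refinement stays within the bracketing second
  extr <- extrapolate_to_hrmax(fit, prot, 190, x_start, rs$end, refine = TRUE)
  ext <- extrapolate_to_hrmax(fit, prot, 190, x_start, rs$end)
  expect_lte(extr$t_hrmax_model, ext$t_hrmax_model)
  expect_gt(extr$t_hrmax_model, ext$t_hrmax_model - 1)
})

test_that("raising the HRmax target never lowers crossing time or VO2max", {
  truth <- sample_cohort(1, seed = 12)[[1]]
  rec <- generate_test(truth, mode = "submaximal_80", noise = FALSE)
  targets <- c(175, 185, 195)
  preds <- lapply(targets, function(tg)
    smo_predict(rec$hr, rec$vo2, rec$protocol, hrmax_target = tg))
  t_cross <- sapply(preds, `[[`, "t_hrmax_model")
  vo2 <- sapply(preds, `[[`, "vo2max_predicted")
  expect_true(all(diff(t_cross) >= 0))
  expect_true(all(diff(vo2) >= 0))
})

test_that("SMO recovers the constructed truth on noise-free data", {
  truth <- sample_cohort(1, seed = 7)[[1]]
  rec <- generate_test(truth, mode = "submaximal_80", noise = FALSE)
  pred <- smo_predict(rec$hr, rec$vo2, rec$protocol, truth$subject,
                      hrmax_target = truth$true_hrmax)
  expect_true(pred$reached)
  expect_lt(relative_error(truth$true_vo2max, pred$vo2max_predicted), 1)
  expect_equal(diff(pred$hr_extrapolation$time_s),
               rep(1, nrow(pred$hr_extrapolation) - 1))   # exact 1-s grid
})

test_that("the pipeline is deterministic and tags stage failures", {
  truth <- sample_cohort(1, seed = 19)[[1]]
  rec <- generate_test(truth, mode = "submaximal_80", seed = 19)
  hr <- moving_average(rec$hr); vo2 <- moving_average(rec$vo2)
  p1 <- smo_predict(hr, vo2, rec$protocol, truth$subject)
  p2 <- smo_predict(hr, vo2, rec$protocol, truth$subject)
  expect_identical(p1$vo2max_predicted, p2$vo2max_predicted)
  expect_identical(p1$t_hrmax_model, p2$t_hrmax_model)
  expect_identical(coef(p1$hr_fit), coef(p2$hr_fit))
  expect_error(smo_predict(hr, vo2, rec$protocol), "subject or hrmax_target")
})

test_that("a record without recovery still runs, with a warning", {
  truth <- sample_cohort(1, seed = 23)[[1]]
  rec <- generate_test(truth, mode = "submaximal_80", noise = FALSE)
  keep <- rec$hr$phase != "recovery"
  hr <- physio_series(rec$hr$time_s[keep], rec$hr$value[keep], "HR",
                      rec$hr$phase[keep])
  vo2 <- physio_series(rec$vo2$time_s[keep], rec$vo2$value[keep], "VO2",
                       rec$vo2$phase[keep])
  expect_warning(
    pred <- smo_predict(hr, vo2, rec$protocol, truth$subject,
                        hrmax_target = truth$true_hrmax),
    "no recovery")
  expect_lt(relative_error(truth$true_vo2max, pred$vo2max_predicted), 1)
})

test_that("extrapolated recovery decays to the recovery steady state", {
  truth <- sample_cohort(1, seed = 31)[[1]]
  rec <- generate_test(truth, mode = "submaximal_80", noise = FALSE)
  pred <- smo_predict(rec$hr, rec$vo2, rec$protocol, truth$subject,
                      hrmax_target = truth$true_hrmax)
  recov <- extrapolate_recovery(pred, recovery_power = 50, duration_s = 3000)
  hr_ss <- pred$hr_fit$params$X0 + pred$hr_fit$params$K * 50
  vo2_ss <- pred$vo2_fit$params$X0 + pred$vo2_fit$params$K * 50
  n <- nrow(recov)
  expect_equal(recov$hr_bpm[n], hr_ss, tolerance = 1e-3)
  expect_equal(recov$vo2_L_min[n], vo2_ss, tolerance = 1e-4)
  # monotone decrease when starting above the steady state (non-strict at
  # the plateau, where steps fall below floating-point resolution)
  expect_true(all(diff(recov$hr_bpm) <= 1e-9))
  expect_true(all(diff(recov$vo2_L_min) <= 1e-9))
  expect_true(all(diff(recov$hr_bpm[1:60]) < 0))
  expect_equal(nrow(extrapolate_recovery(pred, duration_s = 0)), 0)
})
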