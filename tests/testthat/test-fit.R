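test_that("local-linear derivative is exact on polynomials of degree <= 1", {
  expect_equal(estimate_derivative(rep(5, 20), 7), rep(0, 20))
  d <- estimate_derivative(3 + 0.25 * (0:29), 7)
  expect_equal(d, rep(0.25, 30))
  # irregular sampling with explicit times
  t <- sort(runif(25, 0, 50))
  expect_equal(estimate_derivative(2 * t + 1, 5, times = t), rep(2, 25))
  expect_error(estimate_derivative(1:20, 6), "odd")
  expect_error(estimate_derivative(1:2, 3), "3 samples")
  expect_error(estimate_derivative(1:5, 7), "exceeds")
})

test_that("derivative estimate tracks the analytic model derivative", {
  prot <- ref_protocol()
  pars <- ref_hr_params()
  ser <- sim_series(pars, prot)
  d <- estimate_derivative(ser, 7)
  truth <- submax:::kinetics_rhs(pars, prot, ser$value, ser$time_s)
  # compare away from workload steps (the derivative jumps there)
  p <- power_at(prot, ser$time_s)
  interior <- which(sapply(seq_along(p), function(i) {
    idx <- max(1, i - 3):min(length(p), i + 3)
    all(p[idx] == p[i])
  }))
  expect_lt(max(abs(d[interior] - truth[interior])), 0.02)
})

test_that("both estimators recover true parameters from noise-free data", {
  prot <- ref_protocol()
  truth <- c(K = 0.4, tau = 40, X0 = 70)
  ser <- sim_series(ref_hr_params(), prot)
  fd <- fit_kinetics(ser, prot, method = "derivative")
  expect_true(fd$converged)
  expect_lt(max(abs(coef(fd) - truth) / truth), 0.02)
  fn <- fit_kinetics(ser, prot, method = "nls")
  expect_true(fn$converged)
  expect_lt(max(abs(coef(fn) - truth) / truth), 1e-3)
  # nls recovers truth from a poor start too
  fn2 <- fit_kinetics(ser, prot, method = "nls",
                      init = kinetics_params(0.6, 60, 105, "HR"))
  expect_lt(max(abs(coef(fn2) - truth) / truth), 1e-3)
  expect_gt(fd$r_squared, 0.999)
})

test_that("estimators agree with each other on low-noise data", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  set.seed(21)
  ser$value <- ser$value + rnorm(nrow(ser), 0, 0.5)
  ser <- moving_average(ser)
  fd <- fit_kinetics(ser, prot, method = "derivative")
  fn <- fit_kinetics(ser, prot, method = "nls")
  expect_lt(max(abs(coef(fd) - coef(fn)) / coef(fn)), 0.10)
})

test_that("pure noise uncorrelated with workload does not yield dynamics", {
  prot <- ref_protocol()
  set.seed(4)
  ser <- label_phases(
    physio_series(0:protocol_end(prot), 100 + rnorm(protocol_end(prot) + 1), "HR"),
    prot)
  f <- fit_kinetics(ser, prot, method = "derivative")
  if (f$converged) {
    # any apparent gain is an order of magnitude below physiological values
    expect_lt(abs(f$params$K), 0.1)
    expect_lt(f$r_squared, 0.2)       # trajectory explains next to nothing
  } else {
    expect_false(f$converged)
  }
})

test_that("K estimate stays within 10% (median) under 2-bpm noise", {
  prot <- ref_protocol()
  clean <- sim_series(ref_hr_params(), prot)
  errs <- sapply(1:15, function(s) {
    set.seed(100 + s)
    noisy <- clean
    noisy$value <- pmax(noisy$value + rnorm(nrow(noisy), 0, 2), 1)
    f <- fit_kinetics(moving_average(noisy), prot)
    abs(f$params$K - 0.4) / 0.4
  })
  expect_lt(median(errs), 0.10)
})

test_that("tau is scale invariant and K, X0 scale with the series", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  f1 <- fit_kinetics(ser, prot)
  ser2 <- ser
  ser2$value <- ser$value * 3
  f2 <- fit_kinetics(ser2, prot)
  expect_equal(coef(f2)[["tau"]], coef(f1)[["tau"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["K"]], 3 * coef(f1)[["K"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["X0"]], 3 * coef(f1)[["X0"]], tolerance = 1e-6)
})

test_that("simulate-then-refit is a fixed point on noiseless data", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  f1 <- fit_kinetics(ser, prot)
  resim <- sim_series(f1$params, prot)
  f2 <- fit_kinetics(resim, prot)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-3)
})

test_that("fit guards degenerate inputs and invalid initial values", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  expect_error(fit_kinetics(ser, prot, method = "nls", init = list(K = 1)),
               "kinetics_params")
  expect_error(kinetics_params(0.4, -1, 70), "tau")  # tau <= 0 unrepresentable
  flat <- workload_protocol(data.frame(
    kind = c("warmup", "recovery"), duration_s = c(300, 300),
    power_start_W = c(50, 50), increment_W = 0, step_period_s = 60))
  const <- label_phases(physio_series(0:599, rep(90, 600), "HR"), flat)
  expect_error(fit_kinetics(const, flat), "degenerate")
})

test_that("kinetics_fit methods expose the fitted model", {
  prot <- ref_protocol()
  ser <- sim_series(ref_hr_params(), prot)
  f <- fit_kinetics(ser, prot)
  expect_named(coef(f), c("K", "tau", "X0"))
  expect_length(fitted(f), f$n_points)
  expect_equal(fitted(f) + residuals(f), f$data$value)
  pr <- predict(f)
  expect_equal(pr, fitted(f))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(f$n_points, 3L))
  expect_output(print(f), "kinetics fit")
  expect_output(print(summary(f)), "fit span")
})
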