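test_that("Whyte HRmax is the sex-specific linear rule and decreases with age", {
  expect_equal(whyte_hrmax("male", age = 20), 191)
  expect_equal(whyte_hrmax("female", age = 20), 194.2)
  expect_equal(whyte_hrmax("male", age = 1e-9), 202, tolerance = 1e-6)
  s <- subject("a", "female", age = 30)
  expect_equal(whyte_hrmax(s), 216 - 1.09 * 30)
  ages <- seq(18, 70, by = 2)
  expect_true(all(diff(sapply(ages, function(a) whyte_hrmax("male", a))) < 0))
  expect_true(all(diff(sapply(ages, function(a) whyte_hrmax("female", a))) < 0))
})

test_that("Jurca VO2max matches direct evaluation and is affine in inputs", {
  s <- subject("m", "male", age = 20, BMI = 20, RHR = 50, PAS = 0)
  expect_equal(as.numeric(jurca_vo2max(s)), 48.79, tolerance = 1e-9)
  sf <- subject("f", "female", age = 20, BMI = 20, RHR = 50, PAS = 0)
  expect_equal(as.numeric(jurca_vo2max(s)) - as.numeric(jurca_vo2max(sf)),
               3.5 * 2.77)
  s1 <- subject("m", "male", age = 20, BMI = 20, RHR = 50, PAS = 1)
  expect_equal(as.numeric(jurca_vo2max(s1)) - as.numeric(jurca_vo2max(s)), 3.5)
  # finite-difference slopes reproduce the published coefficients
  base <- list(age = 25, BMI = 23, RHR = 60, PAS = 1.06)
  f <- function(age = base$age, BMI = base$BMI, RHR = base$RHR)
    as.numeric(jurca_vo2max(subject("x", "male", age, BMI, RHR, base$PAS)))
  expect_equal(f(age = 26) - f(), 3.5 * -0.10)
  expect_equal(f(BMI = 24) - f(), 3.5 * -0.17)
  expect_equal(f(RHR = 61) - f(), 3.5 * -0.03)
  # L/min conversion only with body mass
  expect_null(attr(jurca_vo2max(s), "L_min"))
  sm <- subject("m", "male", 20, 20, 50, 0, mass_kg = 80)
  expect_equal(attr(jurca_vo2max(sm), "L_min"), 48.79 * 80 / 1000)
  expect_error(jurca_vo2max(subject("m", "male", 20, 20, 50)), "PAS")
})

test_that("relative error reproduces printed per-subject values", {
  expect_equal(round(relative_error(4.34, 3.76), 1), 13.4)
  # two-decimal inputs give 1.98 where 1.9 was printed from unrounded data
  expect_equal(round(relative_error(3.54, 3.47), 2), 1.98)
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(200, 190), 5)
  # scale invariance
  x <- 4.1; y <- 3.6
  expect_equal(relative_error(10 * x, 10 * y), relative_error(x, y))
  expect_error(relative_error(0, 1), "non-zero")
})

test_that("estimator evaluation averages relative errors over a cohort", {
  subs <- list(subject("a", "male", 20), subject("b", "male", 40),
               subject("c", "female", 30))
  exact <- sapply(subs, whyte_hrmax)
  r <- evaluate_estimators(subs, exact, target = "hrmax")
  expect_equal(r$mean_delta[r$formula == "whyte"], 0)
  # known offsets -> hand-computed mean
  measured <- exact * c(1.05, 0.90, 1.00)
  r2 <- evaluate_estimators(subs, measured, target = "hrmax")
  expect_equal(r2$mean_delta[r2$formula == "whyte"],
               mean(100 * abs(measured - exact) / measured))
  expect_error(evaluate_estimators(list(), numeric(0)), "empty")
  # registry is extensible
  register_estimator("tanaka", "hrmax", function(s) 208 - 0.7 * s$age)
  expect_true("tanaka" %in% list_estimators()$name)
  r3 <- evaluate_estimators(subs, exact, target = "hrmax",
                            formulas = c("whyte", "tanaka"))
  expect_equal(nrow(r3), 2)
})

test_that("subject constructor validates resting inputs", {
  expect_error(subject("x", "male", age = 0), "age")
  expect_error(subject("x", "male", age = 25, BMI = -2), "BMI")
  expect_error(subject("x", "male", age = 25, RHR = 0), "RHR")
  expect_equal(unname(jurca_pas_scale()["5"]), 3.03)
})
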