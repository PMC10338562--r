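#' Subject descriptor
#'
#' Demographic and resting inputs for the closed-form estimators: sex, age,
#' body-mass index, resting heart rate and the physical-activity score used
#' by the Jurca VO2max equation. Body mass is optional and only needed to
#' convert ml/kg/min to L/min.
#'
#' @param id subject label.
#' @param sex `"male"` or `"female"`.
#' @param age years, > 0.
#' @param BMI kg/m^2, > 0 (needed by [jurca_vo2max()]).
#' @param RHR resting heart rate, bpm, > 0 (needed by [jurca_vo2max()]).
#' @param PAS physical-activity score (dimensionless; see [jurca_pas_scale()]).
#' @param mass_kg optional body mass, kg.
#' @return An object of class `subject`.
#' @export
subject <- function(id, sex = c("male", "female"), age, BMI = NA_real_,
                    RHR = NA_real_, PAS = NA_real_, mass_kg = NA_real_) {
  sex <- match.arg(sex)
  if (!is.finite(age) || age <= 0) stop("age must be positive")
  if (!is.na(BMI) && BMI <= 0) stop("BMI must be positive")
  if (!is.na(RHR) && RHR <= 0) stop("RHR must be positive")
  structure(list(id = as.character(id), sex = sex, age = age, BMI = BMI,
                 RHR = RHR, PAS = PAS, mass_kg = mass_kg),
            class = "subject")
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("Subject %s: %s, %g y, BMI %g, RHR %g bpm, PAS %g%s\n",
              x$id, x$sex, x$age, x$BMI, x$RHR, x$PAS,
              if (is.na(x$mass_kg)) "" else sprintf(", %g kg", x$mass_kg)))
  invisible(x)
}

#' Whyte age-sex maximal heart rate
#'
#' Linear resting-parameter estimator of maximal heart rate:
#' `202 - 0.55 * age` for males and `216 - 1.09 * age` for females.
#'
#' @param subject a [subject()], or `"male"`/`"female"` with `age` given.
#' @param age years, when `subject` is a sex string.
#' @return Estimated HRmax in bpm.
#' @examples
#' whyte_hrmax("male", age = 20)   # 191
#' @export
whyte_hrmax <- function(subject, age = NULL) {
  if (inherits(subject, "subject")) {
    sex <- subject$sex; age <- subject$age
  } else {
    sex <- match.arg(subject, c("male", "female"))
    if (is.null(age)) stop("age required")
  }
  if (sex == "male") 202 - 0.55 * age else 216 - 1.09 * age
}

#' Jurca physical-activity score scale
#'
#' The category-to-value map for the self-reported physical-activity score
#' of the Jurca resting VO2max equation, following the original publication:
#' five activity categories from inactive (1) to >= 3 h/week of vigorous
#' activity (5).
#'
#' @return Named numeric vector of PAS values for categories 1..5.
#' @export
jurca_pas_scale <- function() {
  c(`1` = 0.00, `2` = 0.32, `3` = 1.06, `4` = 1.76, `5` = 3.03)
}

#' Jurca resting-parameter VO2max
#'
#' The resting/demographic VO2max estimator
#' `3.5 * (18.07 + 2.77 * sex - 0.10 * age - 0.17 * BMI - 0.03 * RHR + PAS)`
#' in ml/kg/min, with `sex = 1` for males and `0` for females. When the
#' subject's body mass is known the absolute value in L/min is attached as
#' attribute `"L_min"`; without body mass no conversion is attempted.
#'
#' @param subject a [subject()] with `BMI`, `RHR` and `PAS` set.
#' @return VO2max in ml/kg/min (attribute `"L_min"` when mass is available).
#' @export
jurca_vo2max <- function(subject) {
  stopifnot(inherits(subject, "subject"))
  if (is.na(subject$PAS)) stop("PAS must be set for the Jurca equation")
  if (is.na(subject$BMI) || is.na(subject$RHR))
    stop("BMI and RHR must be set for the Jurca equation")
  sex01 <- as.numeric(subject$sex == "male")
  v <- 3.5 * (18.07 + 2.77 * sex01 - 0.10 * subject$age -
              0.17 * subject$BMI - 0.03 * subject$RHR + subject$PAS)
  if (!is.na(subject$mass_kg)) attr(v, "L_min") <- v * subject$mass_kg / 1000
  v
}

#' Relative error between an experimental and a predicted value
#'
#' `100 * |experimental - predicted| / experimental`, in percent. The
#' quantity used throughout to compare predicted and measured maxima.
#'
#' @param experimental measured reference value(s); must be non-zero.
#' @param predicted predicted/estimated value(s).
#' @return Relative error(s) in percent.
#' @examples
#' relative_error(4.34, 3.76)  # 13.4 (to one decimal)
#' @export
relative_error <- function(experimental, predicted) {
  if (any(experimental == 0)) stop("experimental value must be non-zero")
  100 * abs(experimental - predicted) / experimental
}

#' Registry of resting-parameter estimators
#'
#' An extensible name -> function registry so additional published HRmax or
#' VO2max formulas can be compared without changing the evaluation harness.
#' Each formula maps a [subject()] to a numeric estimate.
#'
#' @param name formula name.
#' @param target `"hrmax"` or `"vo2max"`.
#' @param fn function of a single [subject()].
#' @return `register_estimator()` returns the registry invisibly;
#'   `list_estimators()` a data.frame of registered formulas.
#' @export
register_estimator <- function(name, target = c("hrmax", "vo2max"), fn) {
  target <- match.arg(target)
  stopifnot(is.function(fn))
  .estimator_registry[[name]] <- list(name = name, target = target, fn = fn)
  invisible(.estimator_registry)
}

.estimator_registry <- new.env(parent = emptyenv())

#' @rdname register_estimator
#' @export
list_estimators <- function() {
  entries <- mget(ls(.estimator_registry), envir = .estimator_registry)
  data.frame(name = vapply(entries, `[[`, "", "name"),
             target = vapply(entries, `[[`, "", "target"),
             row.names = NULL)
}

.onLoad <- function(libname, pkgname) {
  register_estimator("whyte", "hrmax", whyte_hrmax)
  register_estimator("jurca", "vo2max", function(s) as.numeric(jurca_vo2max(s)))
}

#' Evaluate resting-parameter estimators against measured maxima
#'
#' Computes per-subject relative errors of each registered formula against
#' the measured values and summarises them as mean and SD of the relative
#' error across the cohort — the agreement statistic used to select among
#' published formulas.
#'
#' @param subjects list of [subject()]s.
#' @param measured numeric vector of measured maxima, one per subject, in
#'   the formula's units (bpm for HRmax formulas; ml/kg/min for VO2max).
#' @param target `"hrmax"` or `"vo2max"`: which formulas to evaluate.
#' @param formulas formula names; default all registered for the target.
#' @return data.frame with columns `formula`, `mean_delta`, `sd_delta`, `n`.
#' @export
evaluate_estimators <- function(subjects, measured,
                                target = c("hrmax", "vo2max"),
                                formulas = NULL) {
  target <- match.arg(target)
  if (length(subjects) == 0L) stop("empty cohort")
  if (length(measured) != length(subjects))
    stop("one measured value per subject required")
  reg <- mget(ls(.estimator_registry), envir = .estimator_registry)
  reg <- Filter(function(e) e$target == target, reg)
  if (!is.null(formulas)) reg <- reg[formulas]
  if (length(reg) == 0L) stop("no matching formulas registered")
  rows <- lapply(reg, function(e) {
    pred <- vapply(subjects, e$fn, numeric(1))
    d <- relative_error(measured, pred)
    data.frame(formula = e$name, mean_delta = mean(d),
               sd_delta = stats::sd(d), n = length(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
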