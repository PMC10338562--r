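#' Default parameter ranges for the synthetic cohort
#'
#' Sampling configuration for [sample_cohort()]. Demographics match the
#' retrospective reference population (young, physically active males:
#' age 23.5 +/- 2.0 years, BMI 23.9 +/- 3.2 kg/m^2); kinetic parameters are
#' drawn uniformly from documented physiological ranges for first-order
#' heart-rate and oxygen-uptake responses to cycling. The true maximal
#' heart rate is the Whyte estimate plus a subject-specific Gaussian offset
#' (`hrmax_offset_sd`), so the estimated and true HRmax deliberately differ
#' — a known error source of any submaximal prediction.
#'
#' @return A list of ranges/moments consumed by [sample_cohort()].
#' @export
cohort_ranges <- function() {
  list(
    sex = "male",
    age_mean = 23.5, age_sd = 2.0,
    bmi_mean = 23.9, bmi_sd = 3.2,
    rhr_range = c(52, 72),
    mass_range = c(65, 90),
    pas_category = 5,
    K_HR = c(0.3, 0.6), tau_HR = c(25, 60), X0_HR = c(55, 80),
    K_VO2 = c(0.009, 0.012), tau_VO2 = c(25, 50), X0_VO2 = c(0.25, 0.45),
    hrmax_offset_sd = 5,
    noise_sd_hr = 2, noise_sd_vo2 = 0.08
  )
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws `n` synthetic subjects: demographics, first-order kinetic
#' parameters for heart rate and oxygen uptake, a true maximal heart rate,
#' and the implied true VO2max — defined, exactly as in a maximal test, as
#' the model oxygen uptake at the moment the noise-free model heart rate
#' first reaches the subject's true HRmax under the continued incremental
#' ramp. Every downstream module can therefore be validated against known
#' truth without any recorded data.
#'
#' @param n cohort size, >= 1.
#' @param seed optional integer seed for reproducibility.
#' @param ranges configuration, see [cohort_ranges()].
#' @param protocol ramp protocol defining the truth; defaults to the
#'   validation-style step test.
#' @return List of `synthetic_subject_truth` objects with components
#'   `subject`, `hr_params`, `vo2_params`, `true_hrmax`, `true_vo2max`,
#'   `noise_sd` (named vector, HR and VO2).
#' @export
sample_cohort <- function(n, seed = NULL, ranges = cohort_ranges(),
                          protocol = protocol_validation()) {
  if (n < 1) stop("n must be >= 1")
  for (nm in c("K_HR", "tau_HR", "X0_HR", "K_VO2", "tau_VO2", "X0_VO2",
               "rhr_range", "mass_range"))
    if (diff(ranges[[nm]]) < 0) stop("inverted range: ", nm)
  if (!is.null(seed)) set.seed(seed)
  pas <- jurca_pas_scale()[[as.character(ranges$pas_category)]]
  lapply(seq_len(n), function(i) {
    age <- max(18, stats::rnorm(1, ranges$age_mean, ranges$age_sd))
    bmi <- max(17, stats::rnorm(1, ranges$bmi_mean, ranges$bmi_sd))
    X0_HR <- stats::runif(1, ranges$X0_HR[1], ranges$X0_HR[2])
    subj <- subject(id = sprintf("SYN%02d", i), sex = ranges$sex, age = age,
                    BMI = bmi, RHR = round(X0_HR),
                    PAS = pas,
                    mass_kg = stats::runif(1, ranges$mass_range[1],
                                           ranges$mass_range[2]))
    hr_params <- kinetics_params(
      K = stats::runif(1, ranges$K_HR[1], ranges$K_HR[2]),
      tau = stats::runif(1, ranges$tau_HR[1], ranges$tau_HR[2]),
      X0 = X0_HR, variable = "HR")
    vo2_params <- kinetics_params(
      K = stats::runif(1, ranges$K_VO2[1], ranges$K_VO2[2]),
      tau = stats::runif(1, ranges$tau_VO2[1], ranges$tau_VO2[2]),
      X0 = stats::runif(1, ranges$X0_VO2[1], ranges$X0_VO2[2]),
      variable = "VO2")
    true_hrmax <- whyte_hrmax(subj) + stats::rnorm(1, 0, ranges$hrmax_offset_sd)
    truth <- structure(
      list(subject = subj, hr_params = hr_params, vo2_params = vo2_params,
           true_hrmax = true_hrmax, true_vo2max = NA_real_,
           noise_sd = c(HR = ranges$noise_sd_hr, VO2 = ranges$noise_sd_vo2)),
      class = "synthetic_subject_truth")
    truth$true_vo2max <- derive_true_vo2max(truth, protocol)
    truth
  })
}

#' @export
print.synthetic_subject_truth <- function(x, ...) {
  cat(sprintf("Synthetic subject %s: true HRmax %.1f bpm, true VO2max %.3f L/min\n",
              x$subject$id, x$true_hrmax, x$true_vo2max))
  print(x$hr_params)
  print(x$vo2_params)
  invisible(x)
}

#' Re-derive the true VO2max of a synthetic subject
#'
#' Simulates both noise-free models under the (extended) ramp and returns
#' the model VO2 at the first 1-s grid time where model HR reaches the
#' subject's true HRmax. By construction `true_vo2max` equals this value,
#' so truth is always re-derivable from the stored parameters.
#'
#' @param truth a `synthetic_subject_truth`.
#' @param protocol ramp protocol; defaults to the validation step test.
#' @return True VO2max, L/min.
#' @export
derive_true_vo2max <- function(truth, protocol = protocol_validation()) {
  ext <- extend_ramp(protocol)
  t_end <- ramp_reach_time(truth$hr_params, ext, truth$true_hrmax)
  simulate_kinetics(truth$vo2_params, ext, x_start = truth$vo2_params$X0,
                    times = c(0, t_end))$value[2L]
}

# First 1-s grid time at which the noise-free model HR reaches `target`
# under the extended protocol, starting from rest (X0) at t = 0.
ramp_reach_time <- function(hr_params, ext_protocol, target,
                            max_horizon_s = 7200) {
  grid <- seq(0, max_horizon_s, by = 1)
  sim <- simulate_kinetics(hr_params, ext_protocol,
                           x_start = hr_params$X0, times = grid)
  hit <- which(sim$value >= target)
  if (!length(hit))
    stop(sprintf("model HR cannot reach %.1f bpm under this protocol (max %.1f)",
                 target, max(sim$value)))
  rs <- ramp_span(ext_protocol)
  t_hit <- grid[hit[1L]]
  if (t_hit <= rs$start)
    stop("HR target crossed before the ramp; raise the target or lower X0/K")
  t_hit
}

#' Generate a synthetic incremental test recording
#'
#' Simulates heart-rate and oxygen-uptake recordings for one synthetic
#' subject under a step-incremental protocol. In `"maximal"` mode the ramp
#' ends when the noise-free model HR reaches the subject's true HRmax; in
#' `"submaximal_80"` mode it ends when it reaches 80% of the Whyte-estimated
#' HRmax (the proposed submaximal termination rule). A constant-power
#' recovery follows. Independent Gaussian measurement noise is then added
#' per sample and the record is emitted at 1 Hz.
#'
#' @param truth a `synthetic_subject_truth` from [sample_cohort()].
#' @param protocol base step protocol (ramp is truncated at the mode's
#'   stopping point); defaults to the validation test.
#' @param mode `"maximal"` or `"submaximal_80"`.
#' @param seed optional integer seed for the measurement noise.
#' @param noise add measurement noise (disable for noise-free records).
#' @param stop_fraction ramp stopping fraction of estimated HRmax used by
#'   `"submaximal_80"` mode.
#' @return List with `hr` and `vo2` ([physio_series()], phase-labelled),
#'   `protocol` (the truncated [workload_protocol()] actually applied),
#'   `t_end_ramp` and `hr_target`.
#' @export
generate_test <- function(truth, protocol = protocol_validation(),
                          mode = c("maximal", "submaximal_80"), seed = NULL,
                          noise = TRUE, stop_fraction = 0.80) {
  stopifnot(inherits(truth, "synthetic_subject_truth"))
  mode <- match.arg(mode)
  ext <- extend_ramp(protocol)
  target <- if (mode == "maximal") truth$true_hrmax
            else stop_fraction * whyte_hrmax(truth$subject)
  t_end <- ramp_reach_time(truth$hr_params, ext, target)
  rs <- ramp_span(protocol)
  seg <- protocol$segments
  k <- max(which(seg$kind == "ramp"))
  rec <- seg[seg$kind == "recovery", , drop = FALSE]
  recovery_s <- if (nrow(rec)) rec$duration_s[1L] else 300
  recovery_W <- if (nrow(rec)) rec$power_start_W[1L] else 50
  prot_used <- workload_protocol(data.frame(
    kind = c(seg$kind[seq_len(k - 1L)], "ramp", "recovery"),
    duration_s = c(seg$duration_s[seq_len(k - 1L)], t_end - rs$start, recovery_s),
    power_start_W = c(seg$power_start_W[seq_len(k - 1L)], seg$power_start_W[k],
                      recovery_W),
    increment_W = c(seg$increment_W[seq_len(k - 1L)], seg$increment_W[k], 0),
    step_period_s = c(seg$step_period_s[seq_len(k - 1L)], seg$step_period_s[k], 60)),
    name = sprintf("%s (%s)", protocol$name, mode),
    ramp_mode = protocol$ramp_mode)
  times <- seq(0, protocol_end(prot_used), by = 1)
  hr <- simulate_kinetics(truth$hr_params, prot_used,
                          x_start = truth$hr_params$X0, times = times)$value
  vo2 <- simulate_kinetics(truth$vo2_params, prot_used,
                           x_start = truth$vo2_params$X0, times = times)$value
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    hr <- hr + stats::rnorm(length(hr), 0, truth$noise_sd[["HR"]])
    vo2 <- vo2 + stats::rnorm(length(vo2), 0, truth$noise_sd[["VO2"]])
    hr <- pmax(hr, 1e-3)
    vo2 <- pmax(vo2, 1e-3)
  }
  list(hr = label_phases(physio_series(times, hr, "HR"), prot_used),
       vo2 = label_phases(physio_series(times, vo2, "VO2"), prot_used),
       protocol = prot_used, t_end_ramp = t_end, hr_target = target)
}
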