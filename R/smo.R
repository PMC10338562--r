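#' Extrapolate a fitted heart-rate model to an estimated maximum
#'
#' Continues the fitted first-order heart-rate model past the end of the
#' recorded submaximal ramp, under the identical workload increments
#' ([extend_ramp()]), on a 1-second grid, until the model heart rate reaches
#' the target maximum to within the stopping accuracy of 0.1 bpm. The time
#' of this event, `t_HRmax_model`, is the moment at which the predicted
#' VO2max is read off.
#'
#' @param hr_fit a converged `kinetics_fit` for HR.
#' @param protocol the recording's [workload_protocol()] (extended
#'   internally if needed).
#' @param hrmax_target target maximal heart rate, bpm.
#' @param x_start heart rate at `t_start` (bpm); the last smoothed observed
#'   value at the end of the recorded ramp, so model-data offset at the
#'   splice point does not bias the crossing time.
#' @param t_start extrapolation start time, s (end of recorded ramp).
#' @param max_horizon_s extrapolation cap, s; if the target is not reached
#'   within it, `reached = FALSE` is returned (no error).
#' @param tol_bpm stopping accuracy, bpm.
#' @param refine if `TRUE`, bisect within the final second for a sub-second
#'   crossing time.
#' @return An object of class `extrapolation_result`: data.frame `times`/
#'   `values` (1-s grid), `t_hrmax_model`, `reached`, `hrmax_target`.
#' @export
extrapolate_to_hrmax <- function(hr_fit, protocol, hrmax_target, x_start,
                                 t_start, max_horizon_s = 7200,
                                 tol_bpm = 0.1, refine = FALSE) {
  stopifnot(inherits(hr_fit, "kinetics_fit"))
  if (!hr_fit$converged) stop("cannot extrapolate: HR fit did not converge")
  pars <- hr_fit$params
  if (pars$K <= 0 || pars$tau <= 0)
    stop("cannot extrapolate: need K > 0 and tau > 0")
  ext <- if (is.na(protocol$segments$duration_s[nrow(protocol$segments)]) &&
             protocol$segments$kind[nrow(protocol$segments)] == "ramp")
    protocol else extend_ramp(protocol)
  grid <- seq(t_start, t_start + max_horizon_s, by = 1)
  sim <- simulate_kinetics(pars, ext, x_start = x_start, times = grid)
  hit <- which(sim$value >= hrmax_target - tol_bpm)
  reached <- length(hit) > 0L
  t_cross <- if (reached) grid[hit[1L]] else NA_real_
  if (reached && refine && hit[1L] > 1L) {
    f <- function(t) simulate_kinetics(pars, ext, x_start = x_start,
                                       times = c(t_start, t))$value[2L] -
                     (hrmax_target - tol_bpm)
    lo <- grid[hit[1L] - 1L]
    if (f(lo) < 0)
      t_cross <- stats::uniroot(f, c(lo, t_cross), tol = 1e-3)$root
  }
  last <- if (reached) hit[1L] else length(grid)
  structure(list(times = grid[seq_len(last)],
                 values = sim$value[seq_len(last)],
                 t_hrmax_model = t_cross, reached = reached,
                 hrmax_target = hrmax_target, protocol = ext),
            class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat(sprintf("HR extrapolation to %.1f bpm: %s\n", x$hrmax_target,
              if (x$reached)
                sprintf("reached at t = %.1f s (HR = %.2f bpm)",
                        x$t_hrmax_model, x$values[length(x$values)])
              else "NOT reached within horizon"))
  invisible(x)
}

#' Predict VO2max from a submaximal incremental test (SMO)
#'
#' The full submaximal-model prediction pipeline:
#' \enumerate{
#'   \item estimate the subject's maximal heart rate from the Whyte age-sex
#'     formula (or take `hrmax_target` as given);
#'   \item fit the first-order model to the recorded heart-rate series;
#'   \item extrapolate the fitted HR model under the continued ramp until it
#'     reaches the estimated maximum (1-s step, 0.1-bpm accuracy), giving
#'     `t_HRmax_model`;
#'   \item fit the first-order model to the recorded oxygen-uptake series
#'     under the identical workload `P(t)`;
#'   \item simulate the fitted VO2 model forward on the same extended ramp
#'     and read its value at `t_HRmax_model` — the predicted VO2max.
#' }
#'
#' Input series are expected preprocessed (1 Hz, 15-point moving average);
#' set `preprocess = TRUE` to apply [resample_1hz()] and [moving_average()]
#' first. The extrapolations start from the last smoothed observed value at
#' the end of the recorded ramp.
#'
#' @param hr_series,vo2_series [physio_series()] covering warm-up, ramp and
#'   recovery of the submaximal test.
#' @param protocol the [workload_protocol()] of the recording.
#' @param subj a [subject()] (needed unless `hrmax_target` is given).
#' @param hrmax_target override for the estimated maximal heart rate, bpm.
#' @param method estimator passed to [fit_kinetics()].
#' @param embedding_width derivative-estimator window, samples.
#' @param preprocess apply 1-Hz resampling and 15-point smoothing first.
#' @param max_horizon_s extrapolation cap, s.
#' @return An object of class `smo_prediction`: `hrmax_estimate`, `hr_fit`,
#'   `vo2_fit`, `t_hrmax_model`, `vo2max_predicted` (L/min), `reached`, and
#'   the two extrapolated trajectories.
#' @examples
#' \donttest{
#' truth <- sample_cohort(1, seed = 7)[[1]]
#' rec <- generate_test(truth, mode = "submaximal_80", seed = 7)
#' pred <- smo_predict(rec$hr, rec$vo2, rec$protocol, truth$subject)
#' pred
#' }
#' @export
smo_predict <- function(hr_series, vo2_series, protocol, subj = NULL,
                        hrmax_target = NULL,
                        method = c("derivative", "nls"),
                        embedding_width = 7, preprocess = FALSE,
                        max_horizon_s = 7200) {
  method <- match.arg(method)
  stopifnot(inherits(hr_series, "physio_series"),
            inherits(vo2_series, "physio_series"),
            inherits(protocol, "workload_protocol"))
  if (is.null(hrmax_target)) {
    if (is.null(subj)) stop("either a subject or hrmax_target is required")
    hrmax_target <- whyte_hrmax(subj)
  }
  if (preprocess) {
    hr_series <- moving_average(resample_1hz(hr_series))
    vo2_series <- moving_average(resample_1hz(vo2_series))
  }
  if (is.null(hr_series$phase)) hr_series <- label_phases(hr_series, protocol)
  if (is.null(vo2_series$phase)) vo2_series <- label_phases(vo2_series, protocol)
  if (!"recovery" %in% hr_series$phase)
    warning("submaximal record has no recovery phase; fitting warm-up + ramp only")

  hr_fit <- fit_kinetics(hr_series, protocol, method = method,
                         embedding_width = embedding_width)
  if (!hr_fit$converged) stop("SMO stage 2 (HR fit): estimator did not converge")

  rs <- ramp_span(protocol)
  t_start <- min(rs$end, max(hr_series$time_s))
  i_start <- max(which(hr_series$time_s <= t_start))
  x_start_hr <- hr_series$value[i_start]
  ext <- extrapolate_to_hrmax(hr_fit, protocol, hrmax_target,
                              x_start = x_start_hr,
                              t_start = hr_series$time_s[i_start],
                              max_horizon_s = max_horizon_s)
  if (!ext$reached)
    warning("estimated HRmax not reached within the extrapolation horizon")

  vo2_fit <- fit_kinetics(vo2_series, protocol, method = method,
                          embedding_width = embedding_width)
  if (!vo2_fit$converged) stop("SMO stage 4 (VO2 fit): estimator did not converge")

  j_start <- max(which(vo2_series$time_s <= t_start))
  vo2_sim <- simulate_kinetics(vo2_fit$params, ext$protocol,
                               x_start = vo2_series$value[j_start],
                               times = ext$times)
  vo2max_predicted <- if (ext$reached)
    vo2_sim$value[which.min(abs(ext$times - ext$t_hrmax_model))] else NA_real_

  structure(list(hrmax_estimate = hrmax_target, hr_fit = hr_fit,
                 vo2_fit = vo2_fit, t_hrmax_model = ext$t_hrmax_model,
                 vo2max_predicted = vo2max_predicted, reached = ext$reached,
                 hr_extrapolation = data.frame(time_s = ext$times,
                                               hr_bpm = ext$values),
                 vo2_extrapolation = data.frame(time_s = vo2_sim$time_s,
                                                vo2_L_min = vo2_sim$value),
                 subject = subj),
            class = "smo_prediction")
}

#' @export
print.smo_prediction <- function(x, ...) {
  cat("Submaximal-model VO2max prediction\n")
  cat(sprintf("  estimated HRmax:   %.1f bpm\n", x$hrmax_estimate))
  if (x$reached) {
    cat(sprintf("  t_HRmax_model:     %.0f s\n", x$t_hrmax_model))
    cat(sprintf("  predicted VO2max:  %.3f L/min\n", x$vo2max_predicted))
  } else {
    cat("  HRmax not reached within the extrapolation horizon\n")
  }
  cat(sprintf("  HR fit:  K = %.4g bpm/W, tau = %.4g s, X0 = %.4g bpm (R^2 %.3f)\n",
              x$hr_fit$params$K, x$hr_fit$params$tau, x$hr_fit$params$X0,
              x$hr_fit$r_squared))
  cat(sprintf("  VO2 fit: K = %.4g L/min/W, tau = %.4g s, X0 = %.4g L/min (R^2 %.3f)\n",
              x$vo2_fit$params$K, x$vo2_fit$params$tau, x$vo2_fit$params$X0,
              x$vo2_fit$r_squared))
  invisible(x)
}

#' @export
summary.smo_prediction <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.smo_prediction <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$hr_fit$data$time_s, x$hr_fit$data$value, pch = 16, cex = 0.3,
       col = "grey40", xlab = "time (s)", ylab = "HR (bpm)",
       xlim = range(c(x$hr_fit$data$time_s, x$hr_extrapolation$time_s)),
       ylim = range(c(x$hr_fit$data$value, x$hr_extrapolation$hr_bpm)),
       main = "SMO prediction")
  graphics::lines(x$hr_extrapolation, col = "red", lwd = 2)
  graphics::abline(h = x$hrmax_estimate, lty = 2)
  plot(x$vo2_fit$data$time_s, x$vo2_fit$data$value, pch = 16, cex = 0.3,
       col = "grey40", xlab = "time (s)", ylab = "VO2 (L/min)",
       xlim = range(c(x$vo2_fit$data$time_s, x$vo2_extrapolation$time_s)),
       ylim = range(c(x$vo2_fit$data$value, x$vo2_extrapolation$vo2_L_min)))
  graphics::lines(x$vo2_extrapolation, col = "red", lwd = 2)
  if (x$reached) graphics::abline(v = x$t_hrmax_model, lty = 2)
  invisible(x)
}

#' Extrapolate the recovery phase of a prediction
#'
#' Simulates both fitted models under a constant recovery workload after
#' `t_HRmax_model`, giving the expected decay of heart rate and oxygen
#' uptake back towards their recovery steady states.
#'
#' @param prediction an [smo_predict()] result with `reached = TRUE`.
#' @param recovery_power recovery workload, W.
#' @param duration_s recovery duration, s.
#' @return data.frame with `time_s`, `hr_bpm`, `vo2_L_min`.
#' @export
extrapolate_recovery <- function(prediction, recovery_power = 50, duration_s) {
  stopifnot(inherits(prediction, "smo_prediction"))
  if (!prediction$reached) stop("prediction did not reach HRmax")
  if (duration_s <= 0)
    return(data.frame(time_s = numeric(0), hr_bpm = numeric(0),
                      vo2_L_min = numeric(0)))
  t0 <- prediction$t_hrmax_model
  prot <- workload_protocol(data.frame(
    kind = "recovery", duration_s = NA_real_,
    power_start_W = recovery_power, increment_W = 0, step_period_s = 60),
    name = "extrapolated recovery")
  times <- seq(0, duration_s, by = 1)
  n_hr <- nrow(prediction$hr_extrapolation)
  hr <- simulate_kinetics(prediction$hr_fit$params, prot,
                          x_start = prediction$hr_extrapolation$hr_bpm[n_hr],
                          times = times)$value
  n_vo2 <- nrow(prediction$vo2_extrapolation)
  vo2 <- simulate_kinetics(prediction$vo2_fit$params, prot,
                           x_start = prediction$vo2_extrapolation$vo2_L_min[n_vo2],
                           times = times)$value
  data.frame(time_s = t0 + times, hr_bpm = hr, vo2_L_min = vo2)
}
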