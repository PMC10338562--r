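#' Physiological time series
#'
#' A light container for one sampled physiological variable: a data.frame
#' with columns `time_s`, `value` and optionally `phase` (one of
#' `"baseline"`, `"warmup"`, `"ramp"`, `"recovery"` per sample), carrying the
#' variable name (`"HR"` in bpm or `"VO2"` in L/min) as an attribute.
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param value sample values (bpm or L/min); must be positive.
#' @param variable `"HR"` or `"VO2"`.
#' @param phase optional character vector of phase labels per sample.
#' @return An object of class `physio_series` (also a data.frame).
#' @export
physio_series <- function(time_s, value, variable = c("HR", "VO2"),
                          phase = NULL) {
  variable <- match.arg(variable)
  if (length(time_s) != length(value)) stop("time_s and value lengths differ")
  if (length(time_s) && is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("values must be finite and positive")
  out <- data.frame(time_s = as.numeric(time_s), value = as.numeric(value))
  if (!is.null(phase)) {
    if (length(phase) != length(time_s)) stop("phase length mismatch")
    if (!all(phase %in% c("baseline", "warmup", "ramp", "recovery")))
      stop("unknown phase label")
    out$phase <- as.character(phase)
  }
  attr(out, "variable") <- variable
  class(out) <- c("physio_series", "data.frame")
  out
}

#' @export
print.physio_series <- function(x, ...) {
  cat(sprintf("Physio series (%s): %d samples, %g..%g s\n",
              attr(x, "variable"), nrow(x),
              if (nrow(x)) min(x$time_s) else NA,
              if (nrow(x)) max(x$time_s) else NA))
  if (!is.null(x$phase))
    cat("  phases:", paste(rle(x$phase)$values, collapse = " > "), "\n")
  invisible(x)
}

#' Label samples with protocol phases
#'
#' @param series a [physio_series()].
#' @param protocol a [workload_protocol()].
#' @return The series with a `phase` column derived from the protocol
#'   segments containing each sample time.
#' @export
label_phases <- function(series, protocol) {
  stopifnot(inherits(series, "physio_series"),
            inherits(protocol, "workload_protocol"))
  seg <- protocol$segments
  idx <- findInterval(series$time_s, seg$start_s)
  idx[idx < 1L] <- 1L
  series$phase <- seg$kind[idx]
  series
}

#' Resample a recording onto a 1-Hz grid
#'
#' Linear interpolation onto the integer-second grid spanning the recording
#' (from the first whole second at or after the first sample to the last
#' whole second at or before the last sample). Breath-by-breath and
#' beat-to-beat recordings become uniformly sampled series this way.
#'
#' @param series a [physio_series()] with at least 2 samples.
#' @return A 1-Hz [physio_series()].
#' @export
resample_1hz <- function(series) {
  stopifnot(inherits(series, "physio_series"))
  if (nrow(series) < 2L) stop("need at least 2 samples to resample")
  grid <- seq(ceiling(min(series$time_s)), floor(max(series$time_s)), by = 1)
  if (length(grid) < 1L) stop("recording spans less than one second")
  vals <- stats::approx(series$time_s, series$value, xout = grid)$y
  phase <- NULL
  if (!is.null(series$phase)) {
    idx <- findInterval(grid, series$time_s)
    idx[idx < 1L] <- 1L
    phase <- series$phase[idx]
  }
  physio_series(grid, vals, attr(series, "variable"), phase)
}

#' Centred moving-average filter
#'
#' Smooths a series with a centred moving average over `window_pts` samples
#' (15 by default, matching the preprocessing used for breath-by-breath and
#' beat-to-beat recordings at 1 Hz). Near the edges the window shrinks
#' symmetrically, so the output has the same length as the input and no
#' phase lag is introduced.
#'
#' @param series a [physio_series()].
#' @param window_pts odd window length in samples.
#' @return The smoothed [physio_series()].
#' @export
moving_average <- function(series, window_pts = 15) {
  stopifnot(inherits(series, "physio_series"))
  if (window_pts < 1 || window_pts %% 2 == 0)
    stop("window_pts must be odd and >= 1")
  x <- series$value
  n <- length(x)
  h <- (window_pts - 1L) / 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  half <- pmin(h, i - 1L, n - i)
  lo <- i - half
  hi <- i + half
  series$value <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  series
}

#' Instantaneous heart rate from beat times
#'
#' Converts beat-to-beat timestamps (e.g. from an RR-interval monitor) to
#' instantaneous heart rate in bpm at each beat, `60 / RR`, ready for
#' [resample_1hz()].
#'
#' @param beat_times_s strictly increasing beat timestamps, seconds.
#' @return A [physio_series()] of HR at the second beat onwards.
#' @export
hr_from_beats <- function(beat_times_s) {
  if (length(beat_times_s) < 2L) stop("need at least 2 beats")
  rr <- diff(beat_times_s)
  if (any(rr <= 0)) stop("beat times must be strictly increasing")
  physio_series(beat_times_s[-1L], 60 / rr, "HR")
}
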