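#' Workload protocols for incremental cycle-ergometer tests
#'
#' A workload protocol is an ordered, contiguous list of segments describing
#' the ergometer power `P(t)` in watts over the course of a test: an optional
#' resting baseline (0 W), a constant warm-up, an incremental (ramp) phase and
#' a constant recovery. The ramp is a staircase by default (`+increment_W`
#' every `step_period_s` seconds); a continuous linear ramp is available via
#' `ramp_mode = "continuous"` for hardware that ramps smoothly.
#'
#' Time is measured in seconds from recording start; each segment occupies the
#' half-open interval `[start_s, start_s + duration_s)`. The last segment may
#' be open-ended (`duration_s = NA`), which is how extrapolation beyond the
#' recorded test end is represented (see [extend_ramp()]).
#'
#' @param segments a data.frame with columns `kind` (one of `"baseline"`,
#'   `"warmup"`, `"ramp"`, `"recovery"`), `duration_s`, `power_start_W`,
#'   `increment_W` and `step_period_s`. `start_s` is computed by cumulation
#'   and must not be supplied.
#' @param name label for the protocol.
#' @param ramp_mode `"staircase"` (power steps by `increment_W` every
#'   `step_period_s`) or `"continuous"` (linear increase at the same average
#'   rate).
#' @return An object of class `workload_protocol`.
#' @seealso [power_at()], [extend_ramp()], [protocol_retrospective()],
#'   [protocol_validation()]
#' @examples
#' p <- protocol_validation()
#' power_at(p, c(60, 480, 545))
#' @export
workload_protocol <- function(segments, name = "protocol",
                              ramp_mode = c("staircase", "continuous")) {
  ramp_mode <- match.arg(ramp_mode)
  req <- c("kind", "duration_s", "power_start_W", "increment_W", "step_period_s")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("`segments` must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  segments <- as.data.frame(segments)[, req]
  segments$kind <- as.character(segments$kind)
  if (!all(segments$kind %in% c("baseline", "warmup", "ramp", "recovery")))
    stop("segment `kind` must be baseline, warmup, ramp or recovery")
  n <- nrow(segments)
  if (n < 1L) stop("protocol needs at least one segment")
  open <- is.na(segments$duration_s)
  if (any(open[-n])) stop("only the last segment may be open-ended")
  if (any(segments$duration_s[!open] <= 0)) stop("segment durations must be positive")
  if (any(segments$increment_W != 0 & segments$kind != "ramp"))
    stop("increment_W must be 0 for non-ramp segments")
  if (any(segments$kind == "ramp" & segments$step_period_s <= 0))
    stop("step_period_s must be positive in ramp segments")
  if (any(segments$power_start_W < 0) ||
      any(segments$kind == "ramp" & segments$increment_W < 0))
    stop("power must never be negative")
  segments$start_s <- cumsum(c(0, segments$duration_s[-n]))
  structure(
    list(segments = segments[, c("start_s", "duration_s", "kind",
                                 "power_start_W", "increment_W", "step_period_s")],
         name = name, ramp_mode = ramp_mode),
    class = "workload_protocol")
}

#' @export
print.workload_protocol <- function(x, ...) {
  cat("Workload protocol:", x$name,
      sprintf("(%s ramp)\n", x$ramp_mode))
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    dur <- if (is.na(seg$duration_s[i])) "open-ended"
           else sprintf("%g s", seg$duration_s[i])
    extra <- if (seg$kind[i] == "ramp")
      sprintf(" +%g W / %g s", seg$increment_W[i], seg$step_period_s[i]) else ""
    cat(sprintf("  [%6g s] %-9s %s at %g W%s\n", seg$start_s[i], seg$kind[i],
                dur, seg$power_start_W[i], extra))
  }
  invisible(x)
}

#' Total span of a protocol in seconds
#'
#' @param protocol a [workload_protocol()].
#' @return End time in seconds; `Inf` for an open-ended protocol.
#' @export
protocol_end <- function(protocol) {
  seg <- protocol$segments
  n <- nrow(seg)
  if (is.na(seg$duration_s[n])) Inf else seg$start_s[n] + seg$duration_s[n]
}

#' Evaluate the workload at given times
#'
#' Returns the ergometer power in watts at each time. Power is piecewise
#' constant and right-continuous; within a staircase ramp the value is
#' `power_start_W + increment_W * floor((t - start_s) / step_period_s)`.
#'
#' @param protocol a [workload_protocol()].
#' @param t numeric vector of times in seconds, `0 <= t <= protocol_end()`.
#' @return numeric vector of powers in W.
#' @export
power_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "workload_protocol"), is.numeric(t))
  seg <- protocol$segments
  end <- protocol_end(protocol)
  if (any(t < 0) || any(t > end))
    stop("time outside protocol span [0, ", end, "]")
  idx <- findInterval(t, seg$start_s)
  idx[idx < 1L] <- 1L
  rel <- t - seg$start_s[idx]
  p <- seg$power_start_W[idx]
  ramp <- seg$kind[idx] == "ramp" & seg$increment_W[idx] > 0
  if (any(ramp)) {
    if (protocol$ramp_mode == "staircase") {
      p[ramp] <- p[ramp] + seg$increment_W[idx[ramp]] *
        floor(rel[ramp] / seg$step_period_s[idx[ramp]])
    } else {
      p[ramp] <- p[ramp] + seg$increment_W[idx[ramp]] *
        rel[ramp] / seg$step_period_s[idx[ramp]]
    }
  }
  # closed protocols: t == end evaluates the final segment's last value
  at_end <- is.finite(end) & t == end
  if (any(at_end) && seg$kind[nrow(seg)] != "ramp")
    p[at_end] <- seg$power_start_W[nrow(seg)]
  p
}

#' Extend a protocol's ramp indefinitely for extrapolation
#'
#' Drops everything after the last ramp segment and makes the ramp
#' open-ended, keeping the identical increment and step period, so a fitted
#' model can be extrapolated under the continued incremental workload. Any
#' dropped recovery segment is retained as metadata in attribute
#' `"recovery_meta"`.
#'
#' @param protocol a [workload_protocol()] containing a ramp segment.
#' @return A `workload_protocol` whose last segment is the open-ended ramp.
#' @export
extend_ramp <- function(protocol) {
  stopifnot(inherits(protocol, "workload_protocol"))
  seg <- protocol$segments
  k <- max(which(seg$kind == "ramp"), -1L)
  if (k < 1L) stop("protocol has no ramp segment to extend")
  dropped <- if (k < nrow(seg)) seg[(k + 1L):nrow(seg), , drop = FALSE] else NULL
  seg <- seg[seq_len(k), , drop = FALSE]
  seg$duration_s[k] <- NA_real_
  out <- structure(
    list(segments = seg, name = paste0(protocol$name, " (extended ramp)"),
         ramp_mode = protocol$ramp_mode),
    class = "workload_protocol")
  attr(out, "recovery_meta") <- dropped
  out
}

#' Ramp segment boundaries of a protocol
#'
#' @param protocol a [workload_protocol()].
#' @return list with `start` and `end` (possibly `Inf`) of the last ramp
#'   segment, in seconds.
#' @export
ramp_span <- function(protocol) {
  seg <- protocol$segments
  k <- max(which(seg$kind == "ramp"), -1L)
  if (k < 1L) stop("protocol has no ramp segment")
  list(start = seg$start_s[k],
       end = if (is.na(seg$duration_s[k])) Inf
             else seg$start_s[k] + seg$duration_s[k])
}

#' Standard incremental test protocols
#'
#' Builders for the two step-incremental cycling protocols used throughout:
#' the retrospective-style maximal protocol (resting adaptation without
#' cycling, 3 min warm-up at 50 W, +25 W per minute, 3 min cool-down at
#' 50 W) and the validation-style protocol (3 min familiarization, 5 min
#' warm-up at 50 W, +25 W per minute, 5 min recovery at 50 W). The first
#' ramp step sits one increment above the warm-up power.
#'
#' @param baseline_s resting (0 W) adaptation/familiarization duration, s.
#' @param warmup_s warm-up duration, s.
#' @param warmup_W warm-up (and recovery) power, W.
#' @param ramp_duration_s recorded ramp duration, s.
#' @param increment_W ramp power step, W.
#' @param step_period_s time between ramp steps, s.
#' @param recovery_s recovery duration, s.
#' @param recovery_W recovery power, W.
#' @param ramp_mode `"staircase"` or `"continuous"`.
#' @return A [workload_protocol()].
#' @export
protocol_retrospective <- function(baseline_s = 360, warmup_s = 180,
                                   warmup_W = 50, ramp_duration_s = 1200,
                                   increment_W = 25, step_period_s = 60,
                                   recovery_s = 180, recovery_W = 50,
                                   ramp_mode = "staircase") {
  if (any(c(baseline_s, warmup_s, ramp_duration_s, recovery_s) <= 0))
    stop("phase durations must be positive")
  workload_protocol(data.frame(
    kind = c("baseline", "warmup", "ramp", "recovery"),
    duration_s = c(baseline_s, warmup_s, ramp_duration_s, recovery_s),
    power_start_W = c(0, warmup_W, warmup_W + increment_W, recovery_W),
    increment_W = c(0, 0, increment_W, 0),
    step_period_s = c(60, 60, step_period_s, 60)),
    name = "retrospective step test", ramp_mode = ramp_mode)
}

#' @rdname protocol_retrospective
#' @export
protocol_validation <- function(baseline_s = 180, warmup_s = 300,
                                warmup_W = 50, ramp_duration_s = 1200,
                                increment_W = 25, step_period_s = 60,
                                recovery_s = 300, recovery_W = 50,
                                ramp_mode = "staircase") {
  if (any(c(baseline_s, warmup_s, ramp_duration_s, recovery_s) <= 0))
    stop("phase durations must be positive")
  workload_protocol(data.frame(
    kind = c("baseline", "warmup", "ramp", "recovery"),
    duration_s = c(baseline_s, warmup_s, ramp_duration_s, recovery_s),
    power_start_W = c(0, warmup_W, warmup_W + increment_W, recovery_W),
    increment_W = c(0, 0, increment_W, 0),
    step_period_s = c(60, 60, step_period_s, 60)),
    name = "validation step test", ramp_mode = ramp_mode)
}

# Decompose [t0, t1] into maximal intervals on which P(t) is constant
# (staircase) or linear (continuous ramp). Returns data.frame with columns
# start, end, p0 (power at start), rate (W/s within the piece).
power_pieces <- function(protocol, t0, t1) {
  stopifnot(t1 >= t0)
  seg <- protocol$segments
  end <- protocol_end(protocol)
  if (t0 < 0 || t1 > end) stop("time outside protocol span")
  breaks <- seg$start_s
  if (protocol$ramp_mode == "staircase") {
    for (i in which(seg$kind == "ramp" & seg$increment_W > 0)) {
      s <- seg$start_s[i]
      e <- if (is.na(seg$duration_s[i])) t1 else s + seg$duration_s[i]
      e <- min(e, t1)
      if (e > s)
        breaks <- c(breaks, seq(s, e, by = seg$step_period_s[i]))
    }
  }
  breaks <- sort(unique(c(breaks, t0, t1)))
  breaks <- breaks[breaks >= t0 & breaks <= t1]
  if (length(breaks) < 2L) breaks <- c(t0, t1)
  st <- breaks[-length(breaks)]
  en <- breaks[-1L]
  idx <- findInterval(st, seg$start_s)
  rate <- ifelse(seg$kind[idx] == "ramp" & protocol$ramp_mode == "continuous",
                 seg$increment_W[idx] / seg$step_period_s[idx], 0)
  data.frame(start = st, end = en, p0 = power_at(protocol, st), rate = rate)
}
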