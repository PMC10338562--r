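#' Truncate a maximal test at a fraction of maximal heart rate
#'
#' Emulates a submaximal test from a recorded maximal one: the record is cut
#' at the first ramp time where the (smoothed) heart rate reaches
#' `fraction * hrmax_ref`, and a recovery is spliced on by scanning the true
#' recovery phase forward for the first sample whose value is at or below
#' the value at the cut, re-timing that tail to follow the cut contiguously.
#' The workload after the cut is set to the recovery power. The same splice
#' is applied to both variables, each matched on its own value.
#'
#' @param hr_series,vo2_series phase-labelled [physio_series()] of a maximal
#'   test including its recovery.
#' @param protocol the maximal test's [workload_protocol()].
#' @param hrmax_ref reference maximal heart rate, bpm (measured or
#'   estimated).
#' @param fraction truncation fraction of `hrmax_ref`, in (0, 1).
#' @param match `"forward"` (first recovery sample at or below the cut
#'   value) or `"nearest"` (recovery sample closest in value).
#' @param recovery_W workload assigned after the cut, W.
#' @return An object of class `truncation_point`: `fraction`, `t_cut`,
#'   spliced `hr`/`vo2` series and the truncated `protocol`.
#' @export
truncate_at_fraction <- function(hr_series, vo2_series, protocol, hrmax_ref,
                                 fraction, match = c("forward", "nearest"),
                                 recovery_W = 50) {
  match <- match.arg(match)
  stopifnot(inherits(hr_series, "physio_series"),
            inherits(vo2_series, "physio_series"),
            inherits(protocol, "workload_protocol"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (is.null(hr_series$phase) || is.null(vo2_series$phase))
    stop("series must be phase-labelled (see label_phases)")
  target <- fraction * hrmax_ref
  crossed <- which(hr_series$value >= target)
  if (!length(crossed))
    stop(sprintf("%.0f%% of HRmax (%.1f bpm) never attained", 100 * fraction,
                 target))
  i_cut <- crossed[1L]
  if (hr_series$phase[i_cut] != "ramp")
    stop(sprintf("%.0f%% of HRmax crossed in the %s phase; cut must lie in the ramp",
                 100 * fraction, hr_series$phase[i_cut]))
  t_cut <- hr_series$time_s[i_cut]

  splice <- function(series) {
    head_part <- series[series$time_s <= t_cut, , drop = FALSE]
    v_cut <- head_part$value[nrow(head_part)]
    rec <- series[series$phase == "recovery", , drop = FALSE]
    if (!nrow(rec)) stop("series has no recovery phase to splice")
    j <- switch(match,
                forward = which(rec$value <= v_cut)[1L],
                nearest = which.min(abs(rec$value - v_cut)))
    if (is.na(j)) {
      warning("no recovery sample at or below the cut value; splicing at recovery start")
      j <- 1L
    }
    tail_part <- rec[j:nrow(rec), , drop = FALSE]
    dt <- diff(series$time_s[seq_len(min(2L, nrow(series)))])
    step <- if (length(dt)) dt else 1
    tail_part$time_s <- t_cut + step * seq_len(nrow(tail_part))
    tail_part$phase <- "recovery"
    physio_series(c(head_part$time_s, tail_part$time_s),
                  c(head_part$value, tail_part$value),
                  attr(series, "variable"),
                  c(head_part$phase, tail_part$phase))
  }
  hr_spliced <- splice(hr_series)
  vo2_spliced <- splice(vo2_series)

  rs <- ramp_span(protocol)
  seg <- protocol$segments
  k <- max(which(seg$kind == "ramp"))
  rec_len <- max(hr_spliced$time_s, vo2_spliced$time_s) - t_cut
  prot_trunc <- workload_protocol(data.frame(
    kind = c(seg$kind[seq_len(k - 1L)], "ramp", "recovery"),
    duration_s = c(seg$duration_s[seq_len(k - 1L)], t_cut - rs$start,
                   max(rec_len, 1)),
    power_start_W = c(seg$power_start_W[seq_len(k - 1L)], seg$power_start_W[k],
                      recovery_W),
    increment_W = c(seg$increment_W[seq_len(k - 1L)], seg$increment_W[k], 0),
    step_period_s = c(seg$step_period_s[seq_len(k - 1L)],
                      seg$step_period_s[k], 60)),
    name = sprintf("%s (truncated %.0f%%)", protocol$name, 100 * fraction),
    ramp_mode = protocol$ramp_mode)

  structure(list(fraction = fraction, t_cut = t_cut, hr = hr_spliced,
                 vo2 = vo2_spliced, protocol = prot_trunc,
                 hrmax_ref = hrmax_ref),
            class = "truncation_point")
}

#' @export
print.truncation_point <- function(x, ...) {
  cat(sprintf("Truncation at %.0f%% of HRmax (%.1f bpm): t_cut = %g s, %d + %d samples\n",
              100 * x$fraction, x$hrmax_ref, x$t_cut, nrow(x$hr), nrow(x$vo2)))
  invisible(x)
}

#' Retrospective truncation-point study
#'
#' For every subject and every truncation fraction: cut the maximal record
#' at that fraction of maximal heart rate, splice the recovery, run the full
#' submaximal prediction ([smo_predict()]) on the truncated record, and
#' score the predicted VO2max against the subject's reference value with
#' the relative error. Mean error per fraction is then summarised by an
#' ordinary least-squares line on the fraction and by its correlation with
#' the fraction — the evidence base for choosing a termination point.
#'
#' @param cohort list of per-subject records, each a list with components
#'   `hr`, `vo2` (phase-labelled maximal-test [physio_series()]),
#'   `protocol`, `subject` (a [subject()]), `hrmax_measured` (bpm) and
#'   `vo2max_reference` (L/min).
#' @param hrmax_source `"measured"` (truncation and extrapolation use the
#'   per-subject measured HRmax) or `"whyte"` (both use the age-sex
#'   estimate).
#' @param fractions truncation fractions, defaults 0.71..0.95 by 0.01.
#' @param method,embedding_width passed to [smo_predict()].
#' @param max_mean_delta threshold (percent) for [recommend_termination()].
#' @return An object of class `truncation_study`: `table` (fraction,
#'   mean_delta, sd_delta, n), `cells` (per subject x fraction), `fit`
#'   (slope, intercept, r_squared of mean delta on fraction), `correlation`
#'   (pearson/spearman estimates and p-values), `recommended_fraction`,
#'   `hrmax_source`, `failures`.
#' @export
run_truncation_study <- function(cohort,
                                 hrmax_source = c("measured", "whyte"),
                                 fractions = seq(0.71, 0.95, by = 0.01),
                                 method = "derivative", embedding_width = 7,
                                 max_mean_delta = 6) {
  hrmax_source <- match.arg(hrmax_source)
  if (length(cohort) < 1L) stop("empty cohort")
  fractions <- sort(fractions)
  cells <- vector("list", length(cohort) * length(fractions))
  failures <- 0L
  n <- 0L
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]
    hrmax_ref <- switch(hrmax_source,
                        measured = rec$hrmax_measured,
                        whyte = whyte_hrmax(rec$subject))
    for (f in fractions) {
      n <- n + 1L
      cell <- tryCatch({
        tp <- truncate_at_fraction(rec$hr, rec$vo2, rec$protocol,
                                   hrmax_ref, f)
        pred <- smo_predict(tp$hr, tp$vo2, tp$protocol, rec$subject,
                            hrmax_target = hrmax_ref, method = method,
                            embedding_width = embedding_width)
        if (!pred$reached) stop("HRmax not reached in extrapolation")
        data.frame(subject = rec$subject$id, fraction = f,
                   t_cut = tp$t_cut,
                   vo2max_predicted = pred$vo2max_predicted,
                   delta = relative_error(rec$vo2max_reference,
                                          pred$vo2max_predicted))
      }, error = function(e) NULL)
      if (is.null(cell)) failures <- failures + 1L else cells[[n]] <- cell
    }
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells) || !nrow(cells)) stop("every subject x fraction cell failed")
  agg <- stats::aggregate(delta ~ fraction, data = cells,
                          FUN = function(d) c(mean = mean(d), sd = stats::sd(d),
                                              n = length(d)))
  table <- data.frame(fraction = agg$fraction,
                      mean_delta = agg$delta[, "mean"],
                      sd_delta = agg$delta[, "sd"],
                      n = agg$delta[, "n"])
  fit <- NULL; correlation <- NULL
  if (nrow(table) >= 2L) {
    lmfit <- stats::lm(mean_delta ~ fraction, data = table)
    fit <- list(slope = unname(stats::coef(lmfit)[2L]),
                intercept = unname(stats::coef(lmfit)[1L]),
                r_squared = summary(lmfit)$r.squared)
    pear <- stats::cor.test(table$fraction, table$mean_delta, method = "pearson")
    spear <- suppressWarnings(
      stats::cor.test(table$fraction, table$mean_delta, method = "spearman"))
    correlation <- list(pearson = unname(pear$estimate),
                        pearson_p = pear$p.value,
                        spearman = unname(spear$estimate),
                        spearman_p = spear$p.value)
  }
  out <- structure(list(table = table, cells = cells, fit = fit,
                        correlation = correlation,
                        hrmax_source = hrmax_source,
                        failures = failures,
                        recommended_fraction = NA_real_),
                   class = "truncation_study")
  out$recommended_fraction <- tryCatch(
    recommend_termination(out, max_mean_delta),
    warning = function(w) suppressWarnings(recommend_termination(out, max_mean_delta)))
  out
}

#' @export
print.truncation_study <- function(x, ...) {
  cat(sprintf("Truncation-point study (%d fractions, HRmax source: %s)\n",
              nrow(x$table), x$hrmax_source))
  if (!is.null(x$fit))
    cat(sprintf("  mean error vs fraction: slope %.2f %%/unit, R^2 = %.3f\n",
                x$fit$slope, x$fit$r_squared))
  if (!is.null(x$correlation))
    cat(sprintf("  correlation: pearson %.3f (p = %.2g), spearman %.3f (p = %.2g)\n",
                x$correlation$pearson, x$correlation$pearson_p,
                x$correlation$spearman, x$correlation$spearman_p))
  cat(sprintf("  recommended termination fraction: %.2f\n",
              x$recommended_fraction))
  if (x$failures) cat(sprintf("  (%d cells failed and were excluded)\n",
                              x$failures))
  invisible(x)
}

#' @export
plot.truncation_study <- function(x, ...) {
  plot(100 * x$table$fraction, x$table$mean_delta, pch = 16,
       xlab = "truncation point (% of HRmax)",
       ylab = "mean relative error of predicted VO2max (%)",
       main = "Prediction error vs test-termination point", ...)
  if (!is.null(x$fit))  # fitted slope is per unit fraction; x axis is in %
    graphics::abline(a = x$fit$intercept, b = x$fit$slope / 100, col = "red")
  invisible(x)
}

#' Recommend a test-termination fraction
#'
#' The smallest truncation fraction whose mean relative error is at or
#' below `max_mean_delta` percent — ties broken toward the smaller fraction
#' (less exertion). The default threshold of 6% reflects the upper end of
#' the typical 4-6% day-to-day variation in VO2max determination in healthy
#' subjects: a submaximal prediction within that band is as reproducible as
#' the measurement itself.
#'
#' @param result a [run_truncation_study()] result.
#' @param max_mean_delta acceptable mean relative error, percent.
#' @return The recommended fraction; if no fraction qualifies, the largest
#'   studied fraction with a warning.
#' @export
recommend_termination <- function(result, max_mean_delta = 6) {
  stopifnot(inherits(result, "truncation_study"))
  tab <- result$table
  if (!nrow(tab)) stop("empty study result")
  ok <- which(tab$mean_delta <= max_mean_delta)
  if (!length(ok)) {
    warning("no fraction meets the error threshold; returning the largest studied")
    return(tab$fraction[nrow(tab)])
  }
  tab$fraction[ok[1L]]
}
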