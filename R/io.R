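#' Write a test recording to delimited text
#'
#' One row per second: `time_s, power_W, hr_bpm, vo2_L_min, phase`.
#' Comma-separated with dot decimals and a mandatory header by default; the
#' separator is configurable for European exports.
#'
#' @param record list with `hr`, `vo2` ([physio_series()] on a common grid)
#'   and `protocol` (a [workload_protocol()]).
#' @param path output file.
#' @param sep field separator.
#' @return The written data.frame, invisibly.
#' @export
write_record <- function(record, path, sep = ",") {
  hr <- record$hr; vo2 <- record$vo2
  stopifnot(inherits(hr, "physio_series"), inherits(vo2, "physio_series"))
  if (!isTRUE(all.equal(hr$time_s, vo2$time_s)))
    stop("HR and VO2 series must share a time grid to be written together")
  phase <- if (!is.null(hr$phase)) hr$phase
           else label_phases(hr, record$protocol)$phase
  tab <- data.frame(time_s = hr$time_s,
                    power_W = power_at(record$protocol, hr$time_s),
                    hr_bpm = hr$value, vo2_L_min = vo2$value,
                    phase = phase)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Read a test recording from delimited text
#'
#' Reads the tabular record format written by [write_record()], validates
#' it (monotone time, positive values, plausibility screens: HR above 250
#' bpm or VO2 above 8 L/min raise a warning), and reconstructs the workload
#' protocol — either taken from `protocol`, or inferred from the `power_W`
#' and `phase` columns.
#'
#' @param path input file.
#' @param sep field separator.
#' @param protocol optional known [workload_protocol()]; skips inference.
#' @return List with `hr`, `vo2` ([physio_series()]) and `protocol`.
#' @export
read_record <- function(path, sep = ",", protocol = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("time_s", "power_W", "hr_bpm", "vo2_L_min", "phase")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  for (cn in c("time_s", "power_W", "hr_bpm", "vo2_L_min")) {
    bad <- which(!is.finite(tab[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing %s at row(s) %s", cn,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  nonmono <- which(diff(tab$time_s) <= 0)
  if (length(nonmono))
    stop("time_s not strictly increasing at row(s) ",
         paste(utils::head(nonmono + 1L, 5), collapse = ", "))
  if (any(tab$hr_bpm > 250))
    warning("HR above 250 bpm: check units")
  if (any(tab$vo2_L_min > 8))
    warning("VO2 above 8 L/min: check units (expected L/min, not ml/min)")
  if (is.null(protocol)) protocol <- infer_protocol(tab)
  list(hr = physio_series(tab$time_s, tab$hr_bpm, "HR", tab$phase),
       vo2 = physio_series(tab$time_s, tab$vo2_L_min, "VO2", tab$phase),
       protocol = protocol)
}

# Reconstruct a workload protocol from the power and phase columns of a
# record table: one segment per phase run; ramp increment and step period
# taken from the run-length encoding of power inside the ramp.
infer_protocol <- function(tab) {
  runs <- rle(tab$phase)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  dt <- if (nrow(tab) > 1L) stats::median(diff(tab$time_s)) else 1
  seg <- data.frame(kind = runs$values,
                    duration_s = NA_real_, power_start_W = NA_real_,
                    increment_W = 0, step_period_s = 60)
  for (i in seq_along(runs$values)) {
    idx <- starts[i]:ends[i]
    seg$duration_s[i] <- length(idx) * dt
    seg$power_start_W[i] <- tab$power_W[idx[1L]]
    if (runs$values[i] == "ramp") {
      pr <- rle(tab$power_W[idx])
      if (length(pr$values) > 1L) {
        seg$increment_W[i] <- stats::median(diff(pr$values))
        seg$step_period_s[i] <- stats::median(pr$lengths[-length(pr$lengths)]) * dt
      }
    }
  }
  workload_protocol(seg, name = "inferred from record")
}

#' Serialize a prediction or fit to JSON
#'
#' Writes an [smo_predict()] result (or a `kinetics_fit`) as a JSON report
#' embedding the resolved configuration for reproducibility.
#'
#' @param x an `smo_prediction` or `kinetics_fit`.
#' @param path output file; `NULL` returns the JSON string.
#' @param config optional named list echoed into the report (seeds,
#'   estimator settings).
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL, config = list()) {
  payload <-
    if (inherits(x, "smo_prediction")) {
      list(type = "smo_prediction",
           hrmax_estimate_bpm = x$hrmax_estimate,
           t_hrmax_model_s = x$t_hrmax_model,
           vo2max_predicted_L_min = x$vo2max_predicted,
           reached = x$reached,
           hr_fit = fit_payload(x$hr_fit),
           vo2_fit = fit_payload(x$vo2_fit),
           config = config)
    } else if (inherits(x, "kinetics_fit")) {
      c(list(type = "kinetics_fit"), fit_payload(x), list(config = config))
    } else stop("unsupported object")
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

fit_payload <- function(fit) {
  list(estimator = fit$estimator,
       converged = fit$converged,
       params = if (fit$converged)
         list(K = fit$params$K, tau = fit$params$tau, X0 = fit$params$X0,
              variable = fit$params$variable) else NULL,
       r_squared = fit$r_squared,
       residual_sd = fit$residual_sd,
       n_points = fit$n_points,
       embedding_width = fit$embedding_width)
}

#' Printed per-subject VO2max comparison table
#'
#' The published nine-subject validation comparison: experimental VO2max,
#' the submaximal-model prediction, the Jurca resting estimate (all L/min)
#' and their printed relative errors in percent. Shipped as plain text in
#' `inst/extdata/table1_printed.csv` and used by the acceptance checks of
#' the relative-error arithmetic.
#'
#' @return data.frame with columns `subject`, `vo2max_exp`, `vo2max_smo`,
#'   `delta_smo`, `vo2max_jurca`, `delta_jurca`.
#' @export
validation_table <- function() {
  path <- system.file("extdata", "table1_printed.csv", package = "submax",
                      mustWork = TRUE)
  utils::read.csv(path)
}
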