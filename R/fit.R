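#' Local-linear derivative estimation
#'
#' Estimates the first time-derivative of a sampled signal by fitting a
#' first-order polynomial (straight line) by least squares over a centred
#' sliding window of `embedding_width` samples and reading off its slope.
#' At the edges the window shrinks symmetrically, never below 3 points.
#' This is the time-delay-embedding derivative estimator used to linearise
#' the first-order model for regression-based parameter estimation.
#'
#' @param series a [physio_series()] or numeric vector of values (then
#'   `times` must be given).
#' @param embedding_width odd window length, >= 3, <= series length.
#' @param times sample times when `series` is a bare numeric vector.
#' @return Numeric vector of per-sample derivative estimates (signal units
#'   per second).
#' @export
estimate_derivative <- function(series, embedding_width = 7, times = NULL) {
  if (inherits(series, "physio_series")) {
    x <- series$value; t <- series$time_s
  } else {
    x <- as.numeric(series)
    t <- if (is.null(times)) seq_along(x) - 1 else as.numeric(times)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to estimate a derivative")
  if (embedding_width %% 2 == 0 || embedding_width < 3)
    stop("embedding_width must be odd and >= 3")
  if (embedding_width > n) stop("embedding_width exceeds series length")
  h <- (embedding_width - 1L) / 2L
  d <- numeric(n)
  for (i in seq_len(n)) {
    idx <- deriv_window(i, n, h)
    tc <- t[idx] - t[i]
    d[i] <- sum(tc * (x[idx] - mean(x[idx]))) / sum(tc * (tc - mean(tc)))
  }
  d
}

# Centred window of up to 2h+1 samples around i, shrunk symmetrically near
# the edges; at the first/last sample an asymmetric 3-point window is used
# (a centred one does not exist there).
deriv_window <- function(i, n, h) {
  half <- min(h, i - 1L, n - i)
  if (half >= 1L) (i - half):(i + half)
  else if (i == 1L) 1:3 else (n - 2L):n
}

#' Fit the first-order response model to a recorded series
#'
#' Estimates the kinetics parameters `(K, tau, X0)` of the first-order
#' model \eqn{dX/dt + (X - X_0)/\tau = (K/\tau) P(t)} from a recorded
#' physiological series and the workload protocol driving it.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"derivative"`}{(default) The model is linear in the observables
#'   once the derivative is known: \eqn{dX/dt = a X + b P + c} with
#'   \eqn{a = -1/\tau}, \eqn{b = K/\tau}, \eqn{c = X_0/\tau}. The derivative
#'   is estimated by local-linear regression ([estimate_derivative()]) and
#'   ordinary least squares on `[X, P, 1]` yields the coefficients, mapped
#'   back as `tau = -1/a`, `K = -b/a`, `X0 = -c/a`. If `a >= 0` the fit is
#'   flagged `converged = FALSE` (no exception).}
#'   \item{`"nls"`}{Nonlinear least squares (Levenberg-Marquardt) minimising
#'   the squared difference between the closed-form model trajectory —
#'   initial condition pinned to the first observed value — and the data,
#'   over `(K, tau, X0)`. Used as a cross-check of the derivative estimator.}
#' }
#'
#' The fit span covers the warm-up, ramp and recovery phases; the resting
#' baseline (`P = 0`) is excluded by default because pre-exercise
#' anticipatory heart rate does not follow the workload-driven model.
#'
#' @param series a [physio_series()], already resampled to 1 Hz and smoothed.
#' @param protocol the [workload_protocol()] of the recording.
#' @param method `"derivative"` or `"nls"`.
#' @param embedding_width window for the derivative estimator (odd, samples).
#' @param include_baseline include baseline-phase samples in the fit span.
#' @param init optional [kinetics_params()] starting values for `"nls"`;
#'   defaults to a derivative-regression fit.
#' @return An object of class `kinetics_fit` with components `params`
#'   ([kinetics_params()] when converged), `estimator`, `r_squared`
#'   (trajectory coefficient of determination), `residual_sd`, `n_points`,
#'   `embedding_width`, `converged`, `fitted`, `residuals` and the fit data.
#' @seealso [coef.kinetics_fit()], [predict.kinetics_fit()],
#'   [simulate.kinetics_fit()]
#' @examples
#' prot <- protocol_validation(ramp_duration_s = 420)
#' pars <- kinetics_params(0.4, 40, 70, "HR")
#' sim <- simulate_kinetics(pars, prot, times = 0:protocol_end(prot))
#' ser <- label_phases(physio_series(sim$time_s, sim$value, "HR"), prot)
#' fit <- fit_kinetics(ser, prot)
#' coef(fit)
#' @export
fit_kinetics <- function(series, protocol,
                         method = c("derivative", "nls"),
                         embedding_width = 7,
                         include_baseline = FALSE,
                         init = NULL) {
  stopifnot(inherits(series, "physio_series"),
            inherits(protocol, "workload_protocol"))
  method <- match.arg(method)
  variable <- attr(series, "variable")
  if (is.null(series$phase)) series <- label_phases(series, protocol)
  keep <- if (include_baseline) rep(TRUE, nrow(series))
          else series$phase != "baseline"
  dat <- series[keep, , drop = FALSE]
  if (nrow(dat) < 5L) stop("too few samples in the fit span")
  if (length(unique(dat$phase)) < 2L)
    stop("fit span must cover at least 2 protocol phases")
  t <- dat$time_s
  x <- dat$value
  p <- power_at(protocol, t)
  if (stats::sd(p) == 0 || stats::sd(x) == 0)
    stop("degenerate design: workload and response must both vary over the fit span")

  if (method == "derivative") {
    fit <- fit_deriv_reg(x, p, t, embedding_width, variable)
  } else {
    if (is.null(init)) {
      init_fit <- fit_deriv_reg(x, p, t, embedding_width, variable)
      init <- if (init_fit$converged) init_fit$params
              else kinetics_params(K = max((max(x) - min(x)) / max(diff(range(p)), 1), 1e-6),
                                   tau = 30, X0 = min(x), variable = variable)
    }
    if (!inherits(init, "kinetics_params")) stop("init must be kinetics_params")
    fit <- fit_nls_lm(x, p, t, protocol, init, variable)
    fit$embedding_width <- NA_integer_
  }

  fit$n_points <- length(x)
  fit$variable <- variable
  fit$data <- data.frame(time_s = t, value = x, power_W = p)
  fit$protocol <- protocol
  # trajectory fit statistics (model simulated from the first observation)
  if (fit$converged) {
    traj <- simulate_kinetics(fit$params, protocol, x_start = x[1L], times = t)$value
    fit$fitted <- traj
    fit$residuals <- x - traj
    fit$r_squared <- max(0, min(1, 1 - sum(fit$residuals^2) /
                                       sum((x - mean(x))^2)))
    fit$residual_sd <- stats::sd(fit$residuals)
  } else {
    fit$fitted <- rep(NA_real_, length(x))
    fit$residuals <- rep(NA_real_, length(x))
  }
  class(fit) <- "kinetics_fit"
  fit
}

# Derivative-regression estimator: OLS of the local-linear derivative on
# [X, P, 1]; coefficient map tau = -1/a, K = -b/a, X0 = -c/a. Samples whose
# derivative window straddles a workload step are dropped: across a step the
# local-linear slope mixes two exponential branches while P carries only the
# post-step value, which biases tau by several percent if kept.
fit_deriv_reg <- function(x, p, t, embedding_width, variable) {
  dx <- estimate_derivative(x, embedding_width, times = t)
  h <- (embedding_width - 1L) / 2L
  n <- length(x)
  keep <- vapply(seq_len(n), function(i) {
    all(p[deriv_window(i, n, h)] == p[i])
  }, logical(1))
  if (sum(keep) < 10L) keep <- rep(TRUE, n)
  dx <- dx[keep]; x <- x[keep]; p <- p[keep]
  ols <- stats::lm(dx ~ x + p)
  cf <- stats::coef(ols)
  a <- unname(cf["x"]); b <- unname(cf["p"]); c0 <- unname(cf["(Intercept)"])
  converged <- is.finite(a) && a < 0
  params <- NULL
  if (converged) {
    tau <- -1 / a; K <- -b / a; X0 <- -c0 / a
    if (tau > 0 && X0 > 0 && is.finite(K)) {
      params <- kinetics_params(K, tau, X0, variable)
    } else converged <- FALSE
  }
  list(params = params, estimator = "derivative_regression",
       coefficients = c(a = a, b = b, c = c0),
       regression_r_squared = summary(ols)$r.squared,
       r_squared = summary(ols)$r.squared,
       residual_sd = stats::sd(stats::resid(ols)),
       embedding_width = as.integer(embedding_width),
       converged = converged)
}

# Levenberg-Marquardt trajectory fit with x(t1) pinned to the first sample.
fit_nls_lm <- function(x, p, t, protocol, init, variable) {
  resid_fn <- function(par) {
    if (par[2L] <= 0 || par[3L] <= 0) return(rep(1e6, length(x)))
    pars <- kinetics_params(par[1L], par[2L], par[3L], variable)
    x - simulate_kinetics(pars, protocol, x_start = x[1L], times = t)$value
  }
  start <- c(K = init$K, tau = init$tau, X0 = init$X0)
  res <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(-Inf, 1e-3, 1e-9),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  converged <- res$info %in% 1:4 && res$par["tau"] > 0 && res$par["X0"] > 0
  params <- if (converged)
    kinetics_params(unname(res$par["K"]), unname(res$par["tau"]),
                    unname(res$par["X0"]), variable) else NULL
  list(params = params, estimator = "nls",
       coefficients = res$par,
       r_squared = NA_real_, residual_sd = NA_real_,
       converged = converged,
       diagnostics = list(info = res$info, message = res$message,
                          niter = res$niter))
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("First-order kinetics fit (%s, %s)\n", x$variable, x$estimator))
  if (x$converged) {
    print(x$params)
    cat(sprintf("  n = %d, trajectory R^2 = %.4f, residual SD = %.4g\n",
                x$n_points, x$r_squared, x$residual_sd))
  } else {
    cat("  NOT converged (no valid first-order dynamics found)\n")
  }
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.kinetics_fit")
}

#' @export
print.summary.kinetics_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$converged) {
    cat(sprintf("  steady state at 50 W:  %.3f\n",
                f$params$X0 + f$params$K * 50))
    cat(sprintf("  fit span: %g..%g s (%d samples)\n",
                min(f$data$time_s), max(f$data$time_s), f$n_points))
    if (!is.na(f$embedding_width))
      cat(sprintf("  derivative embedding width: %d samples\n", f$embedding_width))
  }
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  if (!object$converged) return(c(K = NA_real_, tau = NA_real_, X0 = NA_real_))
  c(K = object$params$K, tau = object$params$tau, X0 = object$params$X0)
}

#' Predict the model trajectory of a fitted kinetics model
#'
#' @param object a converged [fit_kinetics()] result.
#' @param times time grid, seconds; defaults to the fit span.
#' @param protocol protocol to simulate under; defaults to the fit protocol
#'   (pass an [extend_ramp()]ed protocol to extrapolate).
#' @param x_start initial value at `times[1]`; defaults to the first fitted
#'   value when `times` starts at the fit-span start, else the equilibrium.
#' @param ... unused.
#' @return Numeric vector of model values at `times`.
#' @export
predict.kinetics_fit <- function(object, times = NULL, protocol = NULL,
                                 x_start = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  if (is.null(protocol)) protocol <- object$protocol
  if (is.null(times)) times <- object$data$time_s
  if (is.null(x_start) && isTRUE(all.equal(times[1L], object$data$time_s[1L])))
    x_start <- object$data$value[1L]
  simulate_kinetics(object$params, protocol, x_start = x_start, times = times)$value
}

#' @export
fitted.kinetics_fit <- function(object, ...) object$fitted

#' @export
residuals.kinetics_fit <- function(object, ...) object$residuals

#' Simulate new recordings from a fitted kinetics model
#'
#' Draws `nsim` replicate series: the fitted trajectory plus iid Gaussian
#' noise with the fit's residual standard deviation.
#'
#' @param object a converged [fit_kinetics()] result.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per replicate, `nrow = n_points`.
#' @export
simulate.kinetics_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_points
  out <- as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(n, 0, object$residual_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.kinetics_fit <- function(x, ...) {
  unit <- if (x$variable == "HR") "HR (bpm)" else "VO2 (L/min)"
  plot(x$data$time_s, x$data$value, pch = 16, cex = 0.3, col = "grey40",
       xlab = "time (s)", ylab = unit,
       main = sprintf("First-order kinetics fit (%s)", x$estimator), ...)
  if (x$converged)
    graphics::lines(x$data$time_s, x$fitted, col = "red", lwd = 2)
  invisible(x)
}
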