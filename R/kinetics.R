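#' First-order kinetics parameters
#'
#' Parameters of the first-order differential response model
#' \deqn{dX/dt + (X(t) - X_0)/\tau = (K/\tau) P(t)}
#' for one physiological variable: the gain `K` (steady-state response
#' increase per watt: bpm/W for heart rate, L/min/W for oxygen uptake), the
#' time decay `tau` (seconds; the time to reach about 63% of the asymptotic
#' change after a constant-power step) and the equilibrium value `X0` (the
#' resting value of the variable at `P = 0`).
#'
#' @param K gain (bpm/W or L·min^-1/W); finite.
#' @param tau time decay in seconds; must be positive.
#' @param X0 equilibrium value at zero power (bpm or L/min); must be positive.
#' @param variable `"HR"` or `"VO2"`.
#' @return An object of class `kinetics_params`.
#' @examples
#' kinetics_params(K = 0.4, tau = 40, X0 = 70, variable = "HR")
#' @export
kinetics_params <- function(K, tau, X0, variable = c("HR", "VO2")) {
  variable <- match.arg(variable)
  if (!is.finite(K)) stop("K must be finite")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(X0) || X0 <= 0) stop("X0 must be positive")
  structure(list(K = K, tau = tau, X0 = X0, variable = variable),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  unit <- if (x$variable == "HR") c("bpm/W", "bpm") else c("L/min/W", "L/min")
  cat(sprintf("%s kinetics: K = %g %s, tau = %g s, X0 = %g %s\n",
              x$variable, x$K, unit[1], x$tau, x$X0, unit[2]))
  invisible(x)
}

#' Closed-form solution of the response model over one segment
#'
#' Exact solution of the first-order model for a workload that is constant
#' or linear in time within the segment, `P(t) = p0 + r t`:
#' \deqn{X(dt) = X_0 + K (p_0 + r\,dt) - K r \tau +
#'   (x_{init} - X_0 - K p_0 + K r \tau) e^{-dt/\tau}.}
#' At `r = 0` this is the familiar exponential approach to the steady state
#' `X0 + K p0`.
#'
#' @param x_init value at segment start (bpm or L/min).
#' @param p0 power at segment start, W.
#' @param ramp_rate rate of linear power change within the segment, W/s
#'   (0 for constant power).
#' @param params a [kinetics_params()].
#' @param dt elapsed time within the segment, seconds; may be a vector.
#' @return Value(s) of X at `dt`.
#' @export
closed_form_segment <- function(x_init, p0, ramp_rate, params, dt) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(dt < 0)) stop("dt must be non-negative")
  K <- params$K; tau <- params$tau; X0 <- params$X0; r <- ramp_rate
  X0 + K * (p0 + r * dt) - K * r * tau +
    (x_init - X0 - K * p0 + K * r * tau) * exp(-dt / tau)
}

#' Simulate the response model under a workload protocol
#'
#' Chains the exact closed-form solution across the constant/linear-power
#' pieces of the protocol (each staircase step is a constant-power piece),
#' producing a continuous, deterministic trajectory evaluated at `times`.
#'
#' @param params a [kinetics_params()].
#' @param protocol a [workload_protocol()].
#' @param x_start initial value at `times[1]`; defaults to the equilibrium
#'   at the power applied there (`X0 + K * P`).
#' @param times strictly increasing time grid in seconds, within the
#'   (possibly extended) protocol span.
#' @return A data.frame of class `simulated_response` with columns `time_s`
#'   and `value`; the parameters and protocol are kept as attributes.
#' @examples
#' pars <- kinetics_params(0.4, 40, 70, "HR")
#' sim <- simulate_kinetics(pars, protocol_validation(), times = 0:1000)
#' @export
simulate_kinetics <- function(params, protocol, x_start = NULL, times) {
  stopifnot(inherits(params, "kinetics_params"),
            inherits(protocol, "workload_protocol"))
  if (length(times) == 0L) {
    out <- data.frame(time_s = numeric(0), value = numeric(0))
    class(out) <- c("simulated_response", "data.frame")
    return(out)
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  t0 <- times[1L]; t1 <- times[length(times)]
  if (t0 < 0 || t1 > protocol_end(protocol)) stop("grid outside protocol span")
  if (is.null(x_start))
    x_start <- params$X0 + params$K * power_at(protocol, t0)
  if (!is.finite(x_start)) stop("x_start must be finite")
  pieces <- power_pieces(protocol, t0, t1)
  values <- numeric(length(times))
  x <- x_start
  for (i in seq_len(nrow(pieces))) {
    s <- pieces$start[i]; e <- pieces$end[i]
    inside <- which(times >= s & (times < e | i == nrow(pieces)))
    if (length(inside))
      values[inside] <- closed_form_segment(x, pieces$p0[i], pieces$rate[i],
                                            params, times[inside] - s)
    x <- closed_form_segment(x, pieces$p0[i], pieces$rate[i], params, e - s)
  }
  out <- data.frame(time_s = times, value = values)
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol$name
  class(out) <- c("simulated_response", "data.frame")
  out
}

#' Numerical integration of the response model (oracle)
#'
#' Standard adaptive initial-value integration of the model with tight
#' tolerances, integrating piecewise between workload discontinuities so the
#' solver never steps across a power jump. Used as an independent check of
#' the closed-form simulation and as a fallback.
#'
#' @inheritParams simulate_kinetics
#' @param rtol,atol solver tolerances passed to [deSolve::ode()].
#' @return As [simulate_kinetics()].
#' @export
integrate_kinetics_numeric <- function(params, protocol, x_start = NULL, times,
                                       rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "kinetics_params"),
            inherits(protocol, "workload_protocol"))
  if (length(times) == 0L) {
    out <- data.frame(time_s = numeric(0), value = numeric(0))
    class(out) <- c("simulated_response", "data.frame")
    return(out)
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  t0 <- times[1L]; t1 <- times[length(times)]
  if (t0 < 0 || t1 > protocol_end(protocol)) stop("grid outside protocol span")
  if (is.null(x_start))
    x_start <- params$X0 + params$K * power_at(protocol, t0)
  pieces <- power_pieces(protocol, t0, t1)
  K <- params$K; tau <- params$tau; X0 <- params$X0
  values <- numeric(length(times))
  x <- x_start
  for (i in seq_len(nrow(pieces))) {
    s <- pieces$start[i]; e <- pieces$end[i]
    p0 <- pieces$p0[i]; r <- pieces$rate[i]
    inside <- which(times >= s & (times < e | i == nrow(pieces)))
    tt <- sort(unique(c(s, times[inside], e)))
    rhs <- function(t, y, parms)
      list((K * (p0 + r * (t - s)) - (y - X0)) / tau)
    sol <- deSolve::ode(y = c(X = x), times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed on piece ", i, " [", s, ", ", e, "] s")
    if (length(inside))
      values[inside] <- sol[match(times[inside], sol[, "time"]), "X"]
    x <- unname(sol[nrow(sol), "X"])
  }
  out <- data.frame(time_s = times, value = values)
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol$name
  class(out) <- c("simulated_response", "data.frame")
  out
}

# Analytic time derivative of the model trajectory at given times, used as
# an oracle for the empirical derivative estimator: dX/dt = (K P(t) - (X - X0))/tau.
kinetics_rhs <- function(params, protocol, x, t) {
  (params$K * power_at(protocol, t) - (x - params$X0)) / params$tau
}
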