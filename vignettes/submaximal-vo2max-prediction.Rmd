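---
title: "Predicting VO2max from submaximal incremental tests with a first-order kinetics model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting VO2max from submaximal incremental tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(submax)
```

## The problem

Maximal oxygen uptake (VO2max) is the reference measure of cardiorespiratory
fitness, but measuring it directly requires an incremental exercise test
driven to volitional exhaustion — unpleasant for athletes in training and
often inadvisable for clinical populations. `submax` implements a prediction
method that needs only a *submaximal* cycle-ergometer test: the subject stops
when their heart rate reaches 80% of an age-predicted maximum, and the
remainder of the response is supplied by a fitted dynamical model rather than
by the subject's legs.

## The response model

Both heart rate $X = \mathrm{HR}$ (bpm) and oxygen uptake $X = \dot{V}O_2$
(L/min) are modelled as first-order responses to the ergometer workload
$P(t)$ (W), treated as an exogenous excitation:

$$\frac{dX}{dt} + \frac{X(t) - X_0}{\tau} = \frac{K}{\tau}\,P(t).$$

The three parameters have direct physiological readings:

* **$K$** (gain; bpm/W or L·min⁻¹/W): the steady-state rise of the response
  per watt. With $K_{HR} = 2$ bpm/W, a +25 W step eventually raises heart
  rate by 50 bpm, and a +50 W step by 100 bpm — response changes are
  proportional to workload changes.
* **$\tau$** (time decay; s): after a constant-workload step, the response
  covers $1 - e^{-1} \approx 63.2\%$ of its total change in the first
  $\tau$ seconds. Typical values are 25–60 s for HR and 25–50 s for VO2.
* **$X_0$** (equilibrium; bpm or L/min): the resting value at $P = 0$.

For workload that is constant or linear within a segment,
$P(t) = p_0 + r t$, the model has the exact solution

$$X(t) = X_0 + K(p_0 + r t) - K r \tau
  + \bigl(x_{\text{init}} - X_0 - K p_0 + K r \tau\bigr)\,e^{-t/\tau},$$

which `simulate_kinetics()` chains across the segments of a
`workload_protocol` — each step of an incremental staircase is one
constant-power segment — so simulation is exact up to floating point, with
no integration error. `integrate_kinetics_numeric()` provides an
independent adaptive ODE solution (via **deSolve**, integrated piecewise so
the solver never steps across a workload jump, tolerances $10^{-10}$); the
test suite holds the two routes to within $10^{-6}$ of the signal range on
randomised protocols.

```{r identities}
pars <- kinetics_params(K = 2, tau = 30, X0 = 60, variable = "HR")
flat <- function(W) workload_protocol(data.frame(
  kind = "warmup", duration_s = 3600, power_start_W = W,
  increment_W = 0, step_period_s = 60))
base <- simulate_kinetics(pars, flat(50), times = c(0, 3600))$value[2]
up25 <- simulate_kinetics(pars, flat(75), x_start = base, times = c(0, 3600))$value[2]
c(step_gain_bpm = up25 - base)   # K * 25 = 50
```

## Test protocols

The package builds the two step-incremental cycling protocols it was
designed around: `protocol_retrospective()` (up to 6 min resting
adaptation, 3 min warm-up at 50 W, +25 W per minute, 3 min cool-down at
50 W) and `protocol_validation()` (3 min familiarization, 5 min warm-up and
5 min recovery at 50 W, +25 W per minute). "25 W/min" is read as a 25-W
staircase applied every 60 s, because these are step tests; ergometers that
ramp smoothly are covered by `ramp_mode = "continuous"`, which the
closed-form solution handles exactly as a linear-in-time excitation. Times
are seconds from recording start and each segment occupies a half-open
interval, so workload is right-continuous at step edges.

## Preprocessing

Raw recordings are breath-by-breath (VO2) and beat-to-beat (HR).
`resample_1hz()` linearly interpolates both onto an integer-second grid and
`moving_average()` applies a 15-point centred moving average. The window is
centred — with symmetric shrinking at the edges rather than padding — so
smoothing introduces no phase lag and preserves series length; a trailing
window would delay the apparent response by ~7 s and bias $\tau$ upward by
a comparable amount.

## Parameter estimation

The estimation problem the method delegates to is: given the smoothed
series and $P(t)$, recover $(K, \tau, X_0)$. Two estimators are provided.

**Derivative regression** (default). The model is linear once the
derivative is observable: $dX/dt = aX + bP + c$ with $a = -1/\tau$,
$b = K/\tau$, $c = X_0/\tau$. The derivative is estimated by local linear
regression over a centred window of `embedding_width` samples (default 7
at 1 Hz — wide enough to suppress noise, narrow relative to the 25–60 s
dynamics it must follow), and ordinary least squares on $[X, P, 1]$ yields
the coefficients. Two numerical choices matter:

* *Step-straddling windows are excluded.* Across a workload step the local
  slope mixes two exponential branches while the regressor $P$ carries only
  the post-step value; keeping those samples biases $\tau$ by 3–6% even on
  noise-free data, while excluding them brings noise-free recovery to
  ~0.1%. If fewer than 10 samples survive (continuous ramps change power
  every sample) all samples are used.
* *The fit span excludes the resting baseline by default.* At $P = 0$ the
  model predicts $X = X_0$, but pre-exercise anticipatory heart rate is
  driven by arousal, not workload, and violates the model; warm-up, ramp
  and recovery are fitted.

If the estimated $a$ is non-negative (no stable first-order dynamics) the
fit is flagged `converged = FALSE` rather than raising an error, so cohort
runs can skip degenerate records.

**Nonlinear least squares** (`method = "nls"`). Levenberg–Marquardt (via
**minpack.lm**) on the squared distance between the closed-form trajectory
— initial condition pinned to the first observation — and the data. It is
slower but unbiased by derivative estimation, recovers noise-free
parameters to ~$10^{-3}$%, and serves as the cross-check: the suite
requires both estimators to agree on low-noise data. When both converge
the derivative-regression result is reported and NLS kept as a diagnostic.

No per-subject parameter values are published for the cohorts the method
was developed on, so estimator quality is established by simulation:
noise-free recovery within 2% (derivative regression) and 0.1% (NLS), and
under 2-bpm Gaussian noise the median gain error across 50 replicate seeds
stays below 10%.

```{r fit-example}
prot <- protocol_validation(ramp_duration_s = 420)
truthp <- kinetics_params(K = 0.4, tau = 40, X0 = 70, "HR")
sim <- simulate_kinetics(truthp, prot, times = 0:protocol_end(prot))
ser <- label_phases(physio_series(sim$time_s, sim$value, "HR"), prot)
fit <- fit_kinetics(ser, prot)
coef(fit)
```

## The prediction pipeline

`smo_predict()` runs the six-stage submaximal procedure:

1. estimate HRmax from the Whyte age–sex formula
   ($202 - 0.55\,\text{age}$ for males, $216 - 1.09\,\text{age}$ for
   females), unless a target is supplied;
2. fit the HR model to the submaximal record;
3. extrapolate the fitted HR model under the *continued* staircase
   (`extend_ramp()`) on a 1-s grid until it reaches the estimated HRmax
   within 0.1 bpm; that time is $t_{\mathrm{HRmax}}$;
4. fit the VO2 model under the identical $P(t)$;
5. simulate VO2 forward on the same extended ramp and read its value at
   $t_{\mathrm{HRmax}}$ — the predicted VO2max.

Design choices that the procedure's description leaves open, and how they
are resolved here:

* *Splice point.* Extrapolation starts from the last smoothed **observed**
  HR at the end of the recorded ramp, not from the model trajectory, so any
  model–data offset at that moment does not shift the crossing time.
* *Crossing detection.* The first 1-s grid time with model HR
  $\ge$ target $- 0.1$ bpm, reading the 0.1 bpm as the stopping accuracy;
  `refine = TRUE` bisects within the final second when sub-second
  resolution is wanted. The 1-s grid time is within 1 s of a dense
  0.01-s-grid crossing by construction, which the tests verify.
* *Read-out.* VO2max is the simulated VO2 at the grid point nearest
  $t_{\mathrm{HRmax}}$ (the grids coincide, so this is exact).
* *Horizon.* Extrapolation is capped at 7200 s; an unreached target is
  reported (`reached = FALSE`), not raised, since a near-zero fitted gain
  can make any target unreachable.

Raising the HRmax target can only delay the crossing and increase the
read-out — both trajectories increase along the extended ramp — giving a
monotonicity property the tests exercise. The pipeline is deterministic:
identical inputs produce bit-identical predictions.

## Choosing the termination point

Why stop at 80% of estimated HRmax? `run_truncation_study()` reproduces
the retrospective reasoning: take maximal tests, truncate each at 71%,
72%, …, 95% of the subject's HRmax, splice on a recovery (the first true
recovery sample at or below the value at the cut, re-timed to follow it
contiguously — a forward scan; nearest-value matching is available behind
a flag), run the full prediction on each truncated record, and compare
against the measured VO2max. The mean relative error
$\delta = 100\,|X_{exp} - X_{pred}|/X_{exp}$ per fraction is summarised by
a linear fit and its correlation with the fraction (both product–moment
and rank correlations are computed; the headline number is
product–moment). Later truncation leaves more kinetics in the record and
the error falls — on synthetic noisy cohorts the correlation is reliably
negative, which is the property the tests assert; the magnitudes depend on
the data and are not portable numbers.

`recommend_termination()` returns the smallest fraction whose mean error
is at or below a threshold, 6% by default: day-to-day variation of
measured VO2max in healthy subjects is 4–6%, so a prediction within that
band is as reproducible as the measurement. Ties break toward the smaller
fraction (less exertion). Truncation can be referenced to the measured
HRmax (retrospective use) or the Whyte estimate (prospective use);
`hrmax_source` records which.

## The synthetic cohort

No recordings are distributed with the package, so `sample_cohort()` and
`generate_test()` produce model-faithful synthetic subjects with known
ground truth:

* demographics matching the retrospective reference cohort (males,
  age $23.5 \pm 2.0$ y, BMI $23.9 \pm 3.2$ kg/m²; resting HR is set to the
  drawn $X_{0,HR}$ for coherence, physical-activity score at the top Jurca
  category);
* kinetic parameters uniform on $K_{HR} \in [0.3, 0.6]$ bpm/W,
  $\tau_{HR} \in [25, 60]$ s, $X_{0,HR} \in [55, 80]$ bpm,
  $K_{VO_2} \in [0.009, 0.012]$ L·min⁻¹/W, $\tau_{VO_2} \in [25, 50]$ s,
  $X_{0,VO_2} \in [0.25, 0.45]$ L/min — plausible ranges for young active
  adults on a cycle ergometer, documented here as the package's own
  defaults;
* a true HRmax drawn as the Whyte estimate plus a $\mathcal{N}(0, 5^2)$ bpm
  subject offset, so estimated and true HRmax differ the way they do in
  the field and tests can probe the impact of HRmax mis-estimation;
* true VO2max *defined* as the model VO2 at the first 1-s grid time the
  noise-free model HR reaches the true HRmax under the extended ramp —
  re-derivable exactly from the stored parameters;
* iid Gaussian measurement noise, defaults 2 bpm (HR) and 0.08 L/min
  (VO2), matching typical monitor and breath-by-breath scatter after
  1-Hz resampling.

A maximal-mode record ends its ramp at the true HRmax; a submaximal-mode
record at 80% of the *estimated* HRmax, exactly as a subject following the
protocol would. What the generator deliberately does **not** emulate:
the VO2 slow component at high intensity, heart-rate deflection above the
second ventilatory threshold, cardiovascular drift, and irregular
breath-timing artefacts. Passing tests therefore demonstrate that the
machinery is correct and noise-robust under first-order dynamics — not
that real physiology is first-order; on real data the model mismatch at
high intensity is an additional error source that a submaximal test
cannot see.

```{r pipeline}
ranges <- cohort_ranges()
ranges$hrmax_offset_sd <- 0    # make the Whyte estimate exact for this demo
truth <- sample_cohort(1, seed = 7, ranges = ranges)[[1]]
rec <- generate_test(truth, mode = "submaximal_80", seed = 7)
pred <- smo_predict(moving_average(rec$hr), moving_average(rec$vo2),
                    rec$protocol, truth$subject)
c(true = truth$true_vo2max, predicted = pred$vo2max_predicted,
  delta_pct = relative_error(truth$true_vo2max, pred$vo2max_predicted))
```

```{r plot, fig.height = 6}
plot(pred)
```

## Resting-parameter estimators

For comparison, the package carries the two closed-form estimators the
method is benchmarked against: `whyte_hrmax()` and `jurca_vo2max()`
($3.5\,[18.07 + 2.77\,\text{sex} - 0.10\,\text{age} - 0.17\,\text{BMI}
- 0.03\,\text{RHR} + \text{PAS}]$ ml/kg/min). The physical-activity score
is a required numeric input with the original five-category map available
via `jurca_pas_scale()`; no default is silently assumed, and conversion to
L/min is refused without a body mass. `evaluate_estimators()` scores any
registered formula against measured maxima by mean relative error, and
`register_estimator()` lets further published formulas join the
comparison.

## Problem sizes and numerical conventions

The shipped tests run on records of roughly 15–25 simulated minutes at
1 Hz (a few thousand samples per fit), cohorts of up to 17 synthetic
subjects, 25 truncation fractions, and 50 replicate noise seeds for the
Monte-Carlo recovery checks; all randomness is seeded explicitly.
Degenerate inputs fail loudly and early: non-monotone time, non-positive
values, even smoothing windows, constant workload over a fit span (a
collinear design), $\tau \le 0$, and truncation fractions crossed outside
the ramp are all rejected with specific messages rather than propagated
as numerical artefacts.

## Limitations

* The model is first-order by design; it cannot represent a VO2 plateau,
  so predictions near true maximal effort inherit whatever the kinetics
  extrapolate to, and the method's accuracy on populations with altered
  oxygen kinetics is untested here.
* HRmax estimation error from the age formula propagates directly into
  the prediction; the synthetic cohort's HRmax offset exists precisely to
  keep that pathway visible.
* The truncation study's numeric slope, $R^2$ and correlation depend on
  the cohort and noise; only their signs and ordering are stable claims.
* Cycle-ergometer workload only; treadmill excitation is out of scope.
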