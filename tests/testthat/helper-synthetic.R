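# Shared fixtures, all generated in code.

# Noise-free simulated recording of one variable under a protocol, labelled.
sim_series <- function(params, protocol, times = 0:protocol_end(protocol),
                       x_start = NULL) {
  sim <- simulate_kinetics(params, protocol, x_start = x_start, times = times)
  label_phases(physio_series(sim$time_s, sim$value, params$variable), protocol)
}

# Reference test subject used across fitting tests.
ref_hr_params <- function() kinetics_params(K = 0.4, tau = 40, X0 = 70, "HR")
ref_vo2_params <- function() kinetics_params(K = 0.01, tau = 35, X0 = 0.3, "VO2")

# Validation-style protocol truncated in the ramp (submaximal record).
ref_protocol <- function(ramp_s = 420) protocol_validation(ramp_duration_s = ramp_s)

# Small noisy synthetic cohort with maximal tests, for truncation tests.
make_maximal_cohort <- function(n, seed, noise = TRUE) {
  truths <- sample_cohort(n, seed = seed)
  lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    rec <- generate_test(tr, mode = "maximal", seed = seed + 1000L + i,
                         noise = noise)
    hr <- rec$hr; vo2 <- rec$vo2
    if (noise) { hr <- moving_average(hr); vo2 <- moving_average(vo2) }
    list(hr = hr, vo2 = vo2, protocol = rec$protocol, subject = tr$subject,
         hrmax_measured = tr$true_hrmax, vo2max_reference = tr$true_vo2max,
         truth = tr)
  })
}
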