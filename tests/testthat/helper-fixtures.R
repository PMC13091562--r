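# Shared fixtures: small configs and hand-built traces used across tests.

# Minimal config for one condition, deterministic temperature.
quiet_config <- function(cond = condition(20, 1.4), ...) {
  cohort_config(list(cond), n_per_group = 1, seed = 1,
                temp_noise_sd = 0, baseline_core_temp_sd = 0, ...)
}

# A constant-temperature trace (for driving the suppression map directly).
constant_temp_trace <- function(value, t_min = seq(-10, 40, 2),
                                cond = condition(20, 1.4)) {
  structure(list(times = t_min, values = rep(value, length(t_min)),
                 condition = cond, baseline = value, equilibrium = value),
            class = "temperature_trace")
}

# Evaluate the emergence-latency decay curve.
decay_curve <- function(x, d = rorr_decay_default()) d$A * exp(-d$k * x) + d$C

# Evaluate the segmented latency model.
breakpoint_curve <- function(x, b1 = -307.47, b2 = 31.88, b3 = 60.48) {
  b1 * (x < b2) * (x - b2) + b3
}
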