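# Synthetic cohort generator: core-temperature dynamics, righting events,
# burst-suppression EEG and photometry transients.

# Equilibrium core temperature under anesthesia for a condition. Anchored
# mode: for conditions present in the reference table, the equilibrium is
# chosen so the noise-free relaxation hits baseline + delta_t32 exactly at
# isoflurane cessation. Fallback: linear map of ambient temperature.
.anesthesia_equilibrium <- function(config, cond, baseline) {
  row <- .lookup_reference(cond$ambient_temp, cond$iso_conc)
  dur <- config$iso_stop_min - config$iso_start_min
  if (!is.null(row)) {
    frac <- 1 - exp(-config$relaxation_rate * dur)
    baseline + row$delta_t32_c / frac
  } else {
    config$equilibrium_slope * cond$ambient_temp + config$equilibrium_offset
  }
}

.intervention_shift <- function(config, cond, t_min) {
  if (cond$intervention == "none") return(0)
  sgn <- if (cond$intervention == "activate") 1 else -1
  ifelse(t_min >= cond$onset & t_min < cond$offset, sgn * config$intervention_delta, 0)
}

#' Simulate a core-temperature trace
#'
#' Core temperature relaxes toward a state-dependent equilibrium with
#' first-order kinetics dT/dt = -r (T - T_eq). Before isoflurane onset the
#' animal thermoregulates at its baseline; during anesthesia T_eq is the
#' ambient-/dose-dependent anesthetic equilibrium; after cessation T_eq
#' returns to baseline. Interventions shift T_eq by `intervention_delta`
#' during their window. Integration uses exact exponential stepping (the
#' closed-form solution for piecewise-constant T_eq), so the noise-free
#' trajectory equals T_eq + (T0 - T_eq) exp(-r t) within each regime.
#'
#' @param config A [cohort_config()].
#' @param cond A [condition()].
#' @param seed Integer seed, or NULL to use (and advance) the current RNG.
#' @return An object of class `temperature_trace`: list with `times` (min,
#'   relative to isoflurane start), `values` (degC), `condition`, `baseline`
#'   (degC), `equilibrium` (degC, anesthetic equilibrium).
#' @export
simulate_temperature_trace <- function(config, cond, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(cond, "anes_condition"))
  with_seed(seed, {
    times <- seq(config$temp_span_min[1], config$temp_span_min[2],
                 by = config$temp_step_min)
    r <- config$relaxation_rate
    baseline <- config$baseline_core_temp_mean +
      stats::rnorm(1, 0, config$baseline_core_temp_sd)
    t_eq_anes <- .anesthesia_equilibrium(config, cond, baseline)

    latent <- numeric(length(times))
    latent[1] <- baseline
    for (i in seq_along(times)[-1]) {
      t_prev <- times[i - 1]
      anesthetized <- t_prev >= config$iso_start_min & t_prev < config$iso_stop_min
      teq <- (if (anesthetized) t_eq_anes else baseline) +
        .intervention_shift(config, cond, t_prev)
      dt <- times[i] - t_prev
      latent[i] <- teq + (latent[i - 1] - teq) * exp(-r * dt)
    }
    values <- latent + stats::rnorm(length(latent), 0, config$temp_noise_sd)
    values <- pmin(pmax(values, 20), 42)
    structure(list(times = times, values = values, condition = cond,
                   baseline = baseline, equilibrium = t_eq_anes),
              class = "temperature_trace")
  })
}

# Latent core temperature at arbitrary minutes, by linear interpolation.
.temp_at <- function(trace, t_min) {
  stats::approx(trace$times, trace$values, xout = t_min, rule = 2)$y
}

#' Simulate emergence (RORR) latencies from the one-phase decay model
#'
#' Latency = A exp(-k T) + C plus Gaussian noise with
#' sd = `rorr_noise_sd` + `rorr_noise_cv` * |curve value|, truncated below at
#' `rorr_floor`. With both noise terms zero the exact curve value is
#' returned, so the generator and the fitted latency model share one
#' parameterization.
#'
#' @param config A [cohort_config()].
#' @param t_core_at_cessation Core temperature(s) at isoflurane cessation (degC).
#' @param seed Integer seed or NULL.
#' @param n Number of draws per temperature (draws are vectorized over
#'   `t_core_at_cessation` when n = 1).
#' @return Latencies in seconds.
#' @export
simulate_rorr_latency <- function(config, t_core_at_cessation, seed = NULL, n = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(t_core_at_cessation < 20 | t_core_at_cessation > 42))
    stop("t_core_at_cessation must be in [20, 42] degC", call. = FALSE)
  d <- config$rorr_decay
  mu <- d$A * exp(-d$k * t_core_at_cessation) + d$C
  if (n > 1 && length(mu) == 1) mu <- rep(mu, n)
  sdv <- config$rorr_noise_sd + config$rorr_noise_cv * abs(mu)
  with_seed(seed, {
    lat <- mu + stats::rnorm(length(mu), 0, sdv)
    pmax(lat, config$rorr_floor)
  })
}

# Band-limited Gaussian noise via brick-wall spectral synthesis: white noise
# filtered to [lo, hi] Hz in the Fourier domain, rescaled to unit variance.
.band_noise <- function(n, rate, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)                    # two-sided frequency magnitude
  keep <- f >= lo & f <= hi
  if (!any(keep)) return(numeric(n))
  X[!keep] <- 0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# Alternating burst/suppression renewal gate. Segment durations are
# shifted exponentials (minimum `seg_min`, means solved so the long-run
# suppressed fraction equals p at the segment's start time). Returns a
# logical vector, TRUE = burst.
.suppression_gate <- function(times_s, p_fun, supp_mean, seg_min) {
  n <- length(times_s)
  rate <- 1 / (times_s[2] - times_s[1])
  gate <- rep(TRUE, n)
  tc <- times_s[1]
  t_end <- times_s[n]
  suppressing <- FALSE
  while (tc < t_end) {
    p <- p_fun(tc)
    if (p <= 1e-9) {          # no suppression pressure: advance as burst
      tc <- tc + 1
      suppressing <- FALSE
      next
    }
    p <- min(p, 0.999)
    ms <- max(supp_mean, seg_min * p / (1 - p))
    mb <- ms * (1 - p) / p
    dur <- if (suppressing) seg_min + stats::rexp(1, 1 / max(ms - seg_min, 1e-9))
           else             seg_min + stats::rexp(1, 1 / max(mb - seg_min, 1e-9))
    if (suppressing) {
      i0 <- max(1L, ceiling((tc - times_s[1]) * rate) + 1L)
      i1 <- min(n, floor((tc + dur - times_s[1]) * rate))
      if (i1 >= i0) gate[i0:i1] <- FALSE
    }
    tc <- tc + dur
    suppressing <- !suppressing
  }
  gate
}

#' Simulate a burst-suppression EEG record
#'
#' The record is a sum of five band-limited Gaussian components (delta,
#' theta, alpha, beta, gamma) with condition-specific variance weights,
#' multiplied by an alternating burst/suppression renewal gate. The gate's
#' suppressed-time fraction follows a logistic map of the instantaneous core
#' temperature (colder = more suppression), active only while isoflurane is
#' on; suppressed samples are scaled by `suppression_attenuation`.
#'
#' @param config A [cohort_config()].
#' @param cond A [condition()].
#' @param temp_trace A [simulate_temperature_trace()] result (drives the
#'   suppression map).
#' @param seed Integer seed or NULL.
#' @param gating Set FALSE to disable the suppression gate (pure band
#'   mixture, e.g. for spectral calibration work).
#' @return List with `recording` (an `eeg_recording`: `samples` uV, `rate`
#'   Hz, `t0` s relative to isoflurane start, `markers`) and `gate` (logical
#'   ground truth per sample, TRUE = burst).
#' @export
simulate_eeg <- function(config, cond, temp_trace, seed = NULL, gating = TRUE) {
  stopifnot(inherits(config, "cohort_config"), inherits(cond, "anes_condition"),
            inherits(temp_trace, "temperature_trace"))
  if (config$eeg_rate < 200) stop("eeg_rate must be >= 200 Hz", call. = FALSE)
  with_seed(seed, {
    rate <- config$eeg_rate
    span_s <- config$eeg_span_min * 60
    n <- round((span_s[2] - span_s[1]) * rate)
    times_s <- span_s[1] + (seq_len(n) - 1) / rate

    wfun <- config$band_weight_profiles
    w <- if (is.null(wfun)) band_weight_profile(cond$ambient_temp, cond$iso_conc)
         else wfun(cond)
    if (any(w < 0)) stop("band weights must be >= 0", call. = FALSE)
    bands <- eeg_bands()
    bands <- bands[bands$band != "total", ]
    sig <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      wb <- w[[bands$band[b]]]
      if (wb > 0)
        sig <- sig + sqrt(wb) * .band_noise(n, rate, bands$lo[b], bands$hi[b])
    }
    sig <- config$eeg_amplitude_uv * sig

    iso_on <- c(config$iso_start_min, config$iso_stop_min) * 60
    if (gating) {
      sm <- config$suppression_map
      p_fun <- function(t_s) {
        if (t_s < iso_on[1] || t_s >= iso_on[2]) return(0)
        tc <- .temp_at(temp_trace, t_s / 60)
        sm$max_fraction / (1 + exp(sm$steepness * (tc - sm$t_half)))
      }
      gate <- .suppression_gate(times_s, p_fun, config$supp_segment_mean,
                                config$segment_min)
    } else {
      gate <- rep(TRUE, n)
    }
    sig[!gate] <- sig[!gate] * config$suppression_attenuation

    rec <- eeg_recording(sig, rate, t0 = span_s[1],
                         markers = c(iso_start = iso_on[1], iso_stop = iso_on[2]))
    list(recording = rec, gate = gate)
  })
}

#' Simulate a righting-reflex flip log
#'
#' The cage is flipped every `flip_interval_s` seconds; each flip is scored
#' success (righting intact) or fail. True induction latency is Gaussian
#' (`lorr_mean`, `lorr_sd`); true emergence latency comes from
#' [simulate_rorr_latency()] at the condition's calibrated cessation core
#' temperature (reference-table conditions) or at the trace's temperature at
#' cessation otherwise.
#'
#' @inheritParams simulate_eeg
#' @return List with `log` (data.frame time_s, outcome) and `truth` (list
#'   lorr_s, rorr_s, t_core_cessation).
#' @export
simulate_righting <- function(config, cond, temp_trace, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(cond, "anes_condition"))
  with_seed(seed, {
    iso_start <- config$iso_start_min * 60
    iso_stop <- config$iso_stop_min * 60
    lorr_true <- max(config$flip_interval_s,
                     stats::rnorm(1, config$lorr_mean, config$lorr_sd))
    t_cess <- tryCatch(
      calibrated_cessation_temp(cond$ambient_temp, cond$iso_conc, config$rorr_decay),
      error = function(e) .temp_at(temp_trace, config$iso_stop_min))
    rorr_true <- simulate_rorr_latency(config, t_cess)
    t_last <- iso_stop + ceiling(rorr_true / config$flip_interval_s + 2) *
      config$flip_interval_s
    flips <- seq(iso_start - 4 * config$flip_interval_s, t_last,
                 by = config$flip_interval_s)
    outcome <- ifelse(
      flips < iso_start + lorr_true, "success",
      ifelse(flips < iso_stop + rorr_true, "fail", "success"))
    list(log = data.frame(time_s = flips, outcome = outcome,
                          stringsAsFactors = FALSE),
         truth = list(lorr_s = lorr_true, rorr_s = as.numeric(rorr_true),
                      t_core_cessation = t_cess))
  })
}

#' Offset of the double-exponential kernel peak
#'
#' The photometry transient kernel (exp(-t/decay) - exp(-t/rise)) peaks at
#' t = rise * decay / (decay - rise) * log(decay / rise) after onset.
#'
#' @param rise_s,decay_s Kernel time constants (s), decay_s > rise_s.
#' @return Peak offset in seconds.
#' @export
photometry_kernel_peak <- function(rise_s, decay_s) {
  stopifnot(rise_s > 0, decay_s > 0, decay_s != rise_s)
  rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
}

# Kernel normalized to unit peak.
.photometry_kernel <- function(t, rise_s, decay_s) {
  pk_t <- photometry_kernel_peak(rise_s, decay_s)
  pk <- exp(-pk_t / decay_s) - exp(-pk_t / rise_s)
  ifelse(t >= 0, (exp(-t / decay_s) - exp(-t / rise_s)) / pk, 0)
}

#' Simulate a fiber-photometry trace with event-locked transients
#'
#' Baseline fluorescence plus linear drift, Gaussian noise, and one
#' double-exponential transient per event (LORR, RORR) at a configurable
#' onset offset.
#'
#' @param config A [cohort_config()] (its `photometry` list is used).
#' @param events Named numeric vector of event times in seconds relative to
#'   isoflurane start; names among "LORR", "RORR" receive transients, all are
#'   stored as markers. Must be non-empty.
#' @param seed Integer seed or NULL.
#' @param span_s Record span (s); default covers 120 s before isoflurane to
#'   180 s after the last event.
#' @return An object of class `photometry_trace`: `times` (s), `f_raw`
#'   (a.u.), `markers`.
#' @export
simulate_photometry <- function(config, events, seed = NULL, span_s = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!length(events)) stop("events must be non-empty", call. = FALSE)
  ph <- config$photometry
  if (ph$rise_s <= 0 || ph$decay_s <= 0)
    stop("photometry time constants must be > 0", call. = FALSE)
  with_seed(seed, {
    if (is.null(span_s)) span_s <- c(-120, max(events) + 180)
    n <- round((span_s[2] - span_s[1]) * ph$rate)
    times <- span_s[1] + (seq_len(n) - 1) / ph$rate
    f <- ph$baseline + ph$drift_per_s * (times - times[1])
    for (nm in names(events)) {
      off <- switch(nm, LORR = ph$lorr_offset_s, RORR = ph$rorr_offset_s, 0)
      onset <- events[[nm]] + off
      f <- f + ph$amplitude * .photometry_kernel(times - onset, ph$rise_s, ph$decay_s)
    }
    f <- f + stats::rnorm(n, 0, ph$noise_sd)
    structure(list(times = times, f_raw = f, markers = events),
              class = "photometry_trace")
  })
}

#' Generate a full synthetic cohort
#'
#' Simulates `n_per_group` animals for every condition. Per-animal seeds are
#' derived from the master seed by integer hashing ([derive_seed()]), and
#' each modality within an animal gets its own child seed, so the same
#' (config, seed) pair always yields a bit-identical cohort and dropping a
#' modality does not change the others.
#'
#' @param config A [cohort_config()].
#' @param modalities Character subset of
#'   c("temperature", "eeg", "photometry", "righting"). Temperature is always
#'   generated (the other modalities depend on it).
#' @return An object of class `synthetic_cohort`: list with `config` and
#'   `animals`, each animal a list (id, group, condition, temperature,
#'   eeg, gate, righting log, photometry, truth).
#' @export
generate_cohort <- function(config,
                            modalities = c("temperature", "eeg", "photometry", "righting")) {
  stopifnot(inherits(config, "cohort_config"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  animals <- list()
  idx <- 0L
  for (cond in config$conditions) {
    for (j in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      s <- derive_seed(config$seed, idx)
      temp <- simulate_temperature_trace(config, cond, seed = derive_seed(s, 1))
      a <- list(id = sprintf("%s_a%02d", cond$group_label, j),
                group = cond$group_label, condition = cond,
                temperature = temp)
      if ("righting" %in% modalities || "photometry" %in% modalities) {
        ri <- simulate_righting(config, cond, temp, seed = derive_seed(s, 2))
        if ("righting" %in% modalities) a$righting <- ri$log
        a$truth <- ri$truth
      }
      if ("eeg" %in% modalities) {
        ee <- simulate_eeg(config, cond, temp, seed = derive_seed(s, 3))
        a$eeg <- ee$recording
        a$gate <- ee$gate
      }
      if ("photometry" %in% modalities) {
        iso_stop <- config$iso_stop_min * 60
        ev <- c(LORR = a$truth$lorr_s, RORR = iso_stop + a$truth$rorr_s)
        a$photometry <- simulate_photometry(config, ev, seed = derive_seed(s, 4))
      }
      animals[[idx]] <- a
    }
  }
  structure(list(config = config, animals = animals), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$animals), "animals,",
      length(x$config$conditions), "conditions (n =", x$config$n_per_group,
      "per group)\n")
  invisible(x)
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("Core temperature trace: %d samples, t = %g..%g min, baseline %.2f degC\n",
              length(x$times), min(x$times), max(x$times), x$baseline))
  invisible(x)
}
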