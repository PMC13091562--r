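#' Experimental condition descriptor
#'
#' A condition bundles the ambient (chamber) temperature, the isoflurane
#' concentration and an optional neuronal intervention (chemogenetic or
#' optogenetic activation/inhibition, represented purely as a shift of the
#' thermal equilibrium during its time window).
#'
#' @param ambient_temp Ambient temperature T_a in deg C (15-40).
#' @param iso_conc Isoflurane concentration in % v/v (0 = awake, max 3).
#' @param intervention One of "none", "activate", "inhibit".
#' @param onset,offset Intervention window in minutes relative to isoflurane
#'   start (required when intervention != "none"; onset < offset).
#' @param group_label Text label; defaults to "Ta<NN>_iso<X>".
#' @return An object of class `anes_condition`.
#' @examples
#' condition(20, 1.4)
#' condition(25, 1.4, intervention = "activate", onset = -30, offset = 60)
#' @export
condition <- function(ambient_temp, iso_conc, intervention = c("none", "activate", "inhibit"),
                      onset = NULL, offset = NULL, group_label = NULL) {
  intervention <- match.arg(intervention)
  if (!is.numeric(ambient_temp) || ambient_temp < 15 || ambient_temp > 40)
    stop("ambient_temp must be in [15, 40] degC", call. = FALSE)
  if (!is.numeric(iso_conc) || iso_conc < 0 || iso_conc > 3)
    stop("iso_conc must be in [0, 3] % v/v", call. = FALSE)
  if (intervention != "none") {
    if (is.null(onset) || is.null(offset))
      stop("intervention requires onset and offset (min)", call. = FALSE)
    if (onset >= offset) stop("intervention onset must precede offset", call. = FALSE)
  }
  if (is.null(group_label))
    group_label <- sprintf("Ta%g_iso%g", ambient_temp, iso_conc)
  structure(
    list(ambient_temp = ambient_temp, iso_conc = iso_conc,
         intervention = intervention, onset = onset, offset = offset,
         group_label = group_label),
    class = "anes_condition")
}

#' Reference condition table (12 ambient x isoflurane cells)
#'
#' Published group-level summaries for the 4 x 3 design (ambient temperature
#' 20/25/32/36 degC crossed with isoflurane 0.8/1.1/1.4%), n = 7 per cell:
#' the change in core temperature at isoflurane cessation (t = 32 min), the
#' group-mean emergence latency (RORR, seconds from cessation), and the
#' delta-band relative-power weight the EEG generator uses for that cell.
#' Delta weights for the 0.8% column are the published relative powers; the
#' remaining cells carry values chosen on physiological grounds (deeper
#' anesthesia and colder ambient both increase delta dominance).
#'
#' @return A data.frame with columns `ambient_temp`, `iso_conc`,
#'   `delta_t32_c`, `delta_t32_sem`, `rorr_mean_s`, `rorr_sem_s`,
#'   `delta_weight`, `n`.
#' @export
reference_conditions <- function() {
  data.frame(
    ambient_temp = rep(c(20, 25, 32, 36), each = 3),
    iso_conc     = rep(c(0.8, 1.1, 1.4), times = 4),
    delta_t32_c  = c(-3.24, -3.54, -4.51,
                     -1.36, -2.08, -2.22,
                     -0.27, -0.38, -1.11,
                      1.70,  0.44,  0.84),
    delta_t32_sem = c(0.58, 0.69, 0.93,
                      0.21, 0.15, 0.23,
                      0.19, 0.12, 0.36,
                      0.20, 0.38, 0.18),
    rorr_mean_s  = c(348.57, 568.57, 1074.29,
                      99.71, 140.14,  171.57,
                      39.43,  46.00,   45.71,
                       9.43,  10.57,    9.71),
    rorr_sem_s   = c(107.46, 159.21, 227.44,
                      25.45,  16.36,  27.08,
                      16.21,   8.62,  18.47,
                       2.88,   4.61,   3.64),
    delta_weight = c(0.5666, 0.60, 0.63,
                     0.3316, 0.38, 0.42,
                     0.2781, 0.31, 0.34,
                     0.26,   0.28, 0.30),
    n = 7L
  )
}

# Row of reference_conditions() matching (Ta, iso), or NULL.
.lookup_reference <- function(ambient_temp, iso_conc, tol = 1e-6) {
  ref <- reference_conditions()
  hit <- which(abs(ref$ambient_temp - ambient_temp) < tol &
               abs(ref$iso_conc - iso_conc) < tol)
  if (length(hit) == 0) return(NULL)
  ref[hit[1L], ]
}

#' Default one-phase decay parameters for emergence latency
#'
#' Parameters (A, k, C) of the latency model y = A exp(-k T) + C relating
#' emergence latency (s) to core temperature at isoflurane cessation (degC),
#' as fitted across all 12 conditions in the source dataset:
#' A = 20.3e5 s, k = 0.27 /degC, C = -69.06 s.
#'
#' @return A list with elements `A`, `k`, `C`.
#' @export
rorr_decay_default <- function() list(A = 20.3e5, k = 0.27, C = -69.06)

#' Cessation core temperature calibrated to a condition's mean latency
#'
#' Inverts the one-phase decay latency model at the reference table's
#' group-mean RORR for the given condition: T = log(A / (m - C)) / k. This
#' is the core temperature at which the latency curve reproduces that
#' group's published mean emergence latency, and is the temperature the
#' righting-event generator uses for conditions present in the table.
#'
#' @param ambient_temp,iso_conc Condition cell (must be in
#'   [reference_conditions()]).
#' @param decay Decay parameters, default [rorr_decay_default()].
#' @return Core temperature in degC.
#' @export
calibrated_cessation_temp <- function(ambient_temp, iso_conc, decay = rorr_decay_default()) {
  row <- .lookup_reference(ambient_temp, iso_conc)
  if (is.null(row))
    stop("condition (", ambient_temp, ", ", iso_conc, ") not in reference_conditions()",
         call. = FALSE)
  m <- row$rorr_mean_s
  if (m <= decay$C) stop("mean latency below curve plateau; cannot invert", call. = FALSE)
  log(decay$A / (m - decay$C)) / decay$k
}

#' EEG band-weight profile for a condition
#'
#' Relative variance weights of the five band-limited components
#' (delta/theta/alpha/beta/gamma) summed by the EEG generator. Under
#' anesthesia the delta weight comes from the reference table (interpolated
#' over ambient temperature when the cell is absent) and the remainder is
#' split over the other bands in fixed proportions typical of anesthetized
#' rodent EEG; awake recordings use a broadband profile.
#'
#' @param ambient_temp Ambient temperature degC.
#' @param iso_conc Isoflurane % v/v; 0 selects the awake profile.
#' @return Named numeric vector (delta, theta, alpha, beta, gamma), sums to 1.
#' @export
band_weight_profile <- function(ambient_temp, iso_conc) {
  if (iso_conc <= 0) {
    return(c(delta = 0.20, theta = 0.25, alpha = 0.15, beta = 0.20, gamma = 0.20))
  }
  row <- .lookup_reference(ambient_temp, iso_conc)
  if (!is.null(row)) {
    dw <- row$delta_weight
  } else {
    ref <- reference_conditions()
    iso_levels <- sort(unique(ref$iso_conc))
    iso_near <- iso_levels[which.min(abs(iso_levels - iso_conc))]
    sub <- ref[ref$iso_conc == iso_near, ]
    dw <- stats::approx(sub$ambient_temp, sub$delta_weight, xout = ambient_temp,
                        rule = 2)$y
  }
  rest <- 1 - dw
  c(delta = dw,
    theta = 0.32 * rest, alpha = 0.24 * rest,
    beta  = 0.26 * rest, gamma = 0.18 * rest)
}

#' Cohort generator configuration
#'
#' Collects every tunable of the synthetic cohort generator with defaults
#' matching the study design this package models: isoflurane on over
#' t = 0..32 min, core temperature logged every 2 min, cage flipped every
#' 15 s for the righting test, EEG at 500 Hz, photometry at 50 Hz.
#'
#' @param conditions List of [condition()] objects (distinct group labels).
#' @param n_per_group Animals per condition (default 7).
#' @param seed Master seed; per-animal seeds derive via [derive_seed()].
#' @param baseline_core_temp_mean,baseline_core_temp_sd Pre-anesthetic core
#'   temperature distribution (degC), default 36.8 +/- 0.3.
#' @param relaxation_rate First-order relaxation rate of core temperature
#'   toward its equilibrium, 1/min (default 0.15).
#' @param equilibrium_slope,equilibrium_offset Fallback linear map from
#'   ambient to anesthetic equilibrium core temperature (degC/degC, degC),
#'   used only for conditions absent from [reference_conditions()].
#' @param intervention_delta Equilibrium shift (degC) applied during an
#'   intervention window; sign follows the intervention type (+activate,
#'   -inhibit). Default 2.
#' @param temp_noise_sd Measurement noise on logged temperatures (degC).
#' @param temp_span_min,temp_step_min Temperature log span and cadence (min).
#' @param iso_start_min,iso_stop_min Anesthesia window (min).
#' @param rorr_floor Minimum emergence latency (s).
#' @param rorr_noise_sd Absolute latency noise sd (s).
#' @param rorr_noise_cv Latency noise sd as a fraction of the curve value.
#' @param rorr_decay Latency model parameters, see [rorr_decay_default()].
#' @param lorr_mean,lorr_sd Induction (LORR) latency distribution (s).
#' @param flip_interval_s Righting-test flip cadence (s).
#' @param eeg_rate EEG sampling rate, Hz (>= 200 so gamma is below Nyquist).
#' @param eeg_span_min EEG record span (min).
#' @param eeg_amplitude_uv Awake RMS amplitude of the summed EEG (uV).
#' @param band_weight_profiles Optional function(condition) -> named weights;
#'   default uses [band_weight_profile()].
#' @param suppression_map List (t_half degC, steepness 1/degC, max_fraction)
#'   of the logistic map from core temperature to suppressed-time fraction.
#' @param supp_segment_mean Mean suppression segment duration (s).
#' @param segment_min Minimum burst/suppression segment duration (s).
#' @param suppression_attenuation Amplitude factor during suppression (0,1).
#' @param photometry List of photometry generator settings: rate (Hz),
#'   baseline (a.u.), rise_s/decay_s (kernel time constants), amplitude
#'   (a.u.), drift_per_s (a.u./s), noise_sd (a.u.), lorr_offset_s /
#'   rorr_offset_s (transient onset offsets relative to the events).
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(list(condition(20, 1.4)), n_per_group = 2, seed = 7)
#' @export
cohort_config <- function(conditions,
                          n_per_group = 7,
                          seed = 1,
                          baseline_core_temp_mean = 36.8,
                          baseline_core_temp_sd = 0.3,
                          relaxation_rate = 0.15,
                          equilibrium_slope = 0.66,
                          equilibrium_offset = 14.79,
                          intervention_delta = 2,
                          temp_noise_sd = 0.1,
                          temp_span_min = c(-30, 50),
                          temp_step_min = 2,
                          iso_start_min = 0,
                          iso_stop_min = 32,
                          rorr_floor = 1,
                          rorr_noise_sd = 0,
                          rorr_noise_cv = 0.15,
                          rorr_decay = rorr_decay_default(),
                          lorr_mean = 120,
                          lorr_sd = 20,
                          flip_interval_s = 15,
                          eeg_rate = 500,
                          eeg_span_min = c(-5, 35),
                          eeg_amplitude_uv = 40,
                          band_weight_profiles = NULL,
                          suppression_map = list(t_half = 29, steepness = 0.2, max_fraction = 0.9),
                          supp_segment_mean = 1.0,
                          segment_min = 0.5,
                          suppression_attenuation = 0.05,
                          photometry = list(rate = 50, baseline = 100, rise_s = 1,
                                            decay_s = 8, amplitude = 20,
                                            drift_per_s = 0.005, noise_sd = 2,
                                            lorr_offset_s = 0, rorr_offset_s = 0)) {
  if (inherits(conditions, "anes_condition")) conditions <- list(conditions)
  if (!length(conditions) || !all(vapply(conditions, inherits, TRUE, "anes_condition")))
    stop("conditions must be a list of condition() objects", call. = FALSE)
  labels <- vapply(conditions, `[[`, "", "group_label")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ", paste(labels[duplicated(labels)], collapse = ", "),
         call. = FALSE)
  if (relaxation_rate <= 0) stop("relaxation_rate must be > 0", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (eeg_rate < 200) stop("eeg_rate must be >= 200 Hz (gamma band below Nyquist)",
                           call. = FALSE)
  if (suppression_map$max_fraction < 0 || suppression_map$max_fraction > 1)
    stop("suppression max_fraction must be in [0, 1]", call. = FALSE)
  if (suppression_map$steepness <= 0) stop("suppression steepness must be > 0", call. = FALSE)
  if (suppression_attenuation <= 0 || suppression_attenuation >= 1)
    stop("suppression_attenuation must be in (0, 1)", call. = FALSE)
  if (supp_segment_mean <= 0 || segment_min <= 0 || segment_min > supp_segment_mean)
    stop("segment durations must satisfy 0 < segment_min <= supp_segment_mean", call. = FALSE)
  if (photometry$rise_s <= 0 || photometry$decay_s <= 0)
    stop("photometry time constants must be > 0", call. = FALSE)
  if (rorr_noise_sd < 0 || rorr_noise_cv < 0 || rorr_floor <= 0)
    stop("latency noise terms must be >= 0 and rorr_floor > 0", call. = FALSE)
  structure(
    list(conditions = conditions, n_per_group = as.integer(n_per_group), seed = seed,
         baseline_core_temp_mean = baseline_core_temp_mean,
         baseline_core_temp_sd = baseline_core_temp_sd,
         relaxation_rate = relaxation_rate,
         equilibrium_slope = equilibrium_slope,
         equilibrium_offset = equilibrium_offset,
         intervention_delta = intervention_delta,
         temp_noise_sd = temp_noise_sd,
         temp_span_min = temp_span_min, temp_step_min = temp_step_min,
         iso_start_min = iso_start_min, iso_stop_min = iso_stop_min,
         rorr_floor = rorr_floor, rorr_noise_sd = rorr_noise_sd,
         rorr_noise_cv = rorr_noise_cv, rorr_decay = rorr_decay,
         lorr_mean = lorr_mean, lorr_sd = lorr_sd,
         flip_interval_s = flip_interval_s,
         eeg_rate = eeg_rate, eeg_span_min = eeg_span_min,
         eeg_amplitude_uv = eeg_amplitude_uv,
         band_weight_profiles = band_weight_profiles,
         suppression_map = suppression_map,
         supp_segment_mean = supp_segment_mean, segment_min = segment_min,
         suppression_attenuation = suppression_attenuation,
         photometry = photometry),
    class = "cohort_config")
}
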