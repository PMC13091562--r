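# Synthetic cohort generator: temperature dynamics, latencies, EEG gate,
# photometry kernels, determinism.

test_that("noise-free temperature trace matches the closed-form exponential", {
  cfg <- quiet_config(condition(20, 1.4))
  tr <- simulate_temperature_trace(cfg, condition(20, 1.4), seed = 1)
  r <- cfg$relaxation_rate
  T0 <- tr$baseline
  Teq <- tr$equilibrium
  sel <- tr$times >= 0 & tr$times <= 32
  expected <- Teq + (T0 - Teq) * exp(-r * tr$times[sel])
  expect_lt(max(abs(tr$values[sel] - expected)), 1e-6)
  # pre-anesthetic baseline is flat at baseline
  expect_equal(tr$values[tr$times < 0], rep(T0, sum(tr$times < 0)), tolerance = 1e-12)
})

test_that("equilibria anchored to the published endpoint changes", {
  # warmest chamber at the light dose: +1.70 degC at cessation
  cfg <- quiet_config(condition(36, 0.8))
  tr <- simulate_temperature_trace(cfg, condition(36, 0.8), seed = 1)
  expect_equal(tr$values[tr$times == 32] - tr$baseline, 1.70, tolerance = 1e-8)
  # coldest chamber at the deep dose ends below baseline
  cfg2 <- quiet_config(condition(20, 1.4))
  tr2 <- simulate_temperature_trace(cfg2, condition(20, 1.4), seed = 1)
  expect_equal(tr2$values[tr2$times == 32] - tr2$baseline, -4.51, tolerance = 1e-8)
})

test_that("zero relaxation rate is rejected; near-zero rate gives a flat trace", {
  expect_error(cohort_config(list(condition(20, 1.4)), relaxation_rate = 0),
               "relaxation_rate")
  # condition outside the anchored table: equilibrium is the linear map,
  # and a vanishing rate leaves the trace at baseline
  cond <- condition(22, 1.0)
  cfg <- quiet_config(cond, relaxation_rate = 1e-12)
  tr <- simulate_temperature_trace(cfg, cond, seed = 1)
  expect_lt(diff(range(tr$values)), 1e-6)
})

test_that("intervention shifts the equilibrium during its window only", {
  cond_act <- condition(25, 1.4, intervention = "activate", onset = -30, offset = 60)
  cond_ref <- condition(25, 1.4)
  cfg <- quiet_config(cond_ref)
  tr_ref <- simulate_temperature_trace(cfg, cond_ref, seed = 1)
  tr_act <- simulate_temperature_trace(quiet_config(cond_act), cond_act, seed = 1)
  sel <- tr_ref$times > 0 & tr_ref$times <= 32
  expect_true(all(tr_act$values[sel] > tr_ref$values[sel]))
})

test_that("latency generator reproduces the decay curve exactly without noise", {
  cfg <- quiet_config(rorr_noise_sd = 0, rorr_noise_cv = 0)
  expect_equal(simulate_rorr_latency(cfg, 31.88), decay_curve(31.88), tolerance = 1e-12)
  # k = 0 collapses to a constant A + C
  cfg_k0 <- quiet_config(rorr_noise_sd = 0, rorr_noise_cv = 0,
                         rorr_decay = list(A = 100, k = 0, C = 5))
  expect_equal(simulate_rorr_latency(cfg_k0, c(22, 30, 40)), rep(105, 3))
  # monotone decreasing in temperature
  temps <- seq(26, 38, by = 0.5)
  lat <- simulate_rorr_latency(cfg, temps)
  expect_true(all(diff(lat) < 0))
})

test_that("latency sample mean converges to the curve value", {
  cfg <- quiet_config()
  tcal <- calibrated_cessation_temp(20, 1.4)
  means <- vapply(1:200, function(s)
    mean(simulate_rorr_latency(cfg, tcal, seed = derive_seed(123, s), n = 7)),
    numeric(1))
  expect_equal(mean(means), decay_curve(tcal), tolerance = 0.02)
})

test_that("calibrated cessation temperature inverts the latency curve", {
  for (i in seq_len(nrow(reference_conditions()))) {
    row <- reference_conditions()[i, ]
    tc <- calibrated_cessation_temp(row$ambient_temp, row$iso_conc)
    expect_equal(decay_curve(tc), row$rorr_mean_s, tolerance = 1e-8)
  }
})

test_that("suppression gate realizes the configured fraction", {
  # constant temperature at the logistic midpoint: fraction = max_fraction / 2
  cfg <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(0, 12), iso_start_min = 0, iso_stop_min = 12,
                       suppression_map = list(t_half = 29, steepness = 0.2,
                                              max_fraction = 0.7))
  tr <- constant_temp_trace(29, t_min = seq(-5, 15, 2))
  fr <- vapply(1:3, function(s)
    mean(!simulate_eeg(cfg, condition(20, 1.4), tr, seed = s)$gate), numeric(1))
  # ~250 renewal cycles in 12 min: 3 binomial-style SEs ~ 0.09
  expect_true(all(abs(fr - 0.35) < 0.09))
})

test_that("zero suppression pressure gives an all-burst gate", {
  cfg <- cohort_config(list(condition(36, 0.8)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(0, 2),
                       suppression_map = list(t_half = 29, steepness = 0.2,
                                              max_fraction = 0))
  tr <- constant_temp_trace(37)
  ee <- simulate_eeg(cfg, condition(36, 0.8), tr, seed = 1)
  expect_true(all(ee$gate))
})

test_that("delta-dominant weights give delta-dominant spectra", {
  cfg <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(0, 2),
                       band_weight_profiles = function(cond)
                         c(delta = 0.8, theta = 0.05, alpha = 0.05,
                           beta = 0.05, gamma = 0.05))
  tr <- constant_temp_trace(30)
  ee <- simulate_eeg(cfg, condition(20, 1.4), tr, seed = 1, gating = FALSE)
  bp <- compute_band_powers(ee$recording, epoch_len = 30)
  rel <- colMeans(bp[, c("rel_delta", "rel_theta", "rel_alpha", "rel_beta", "rel_gamma")])
  expect_true(all(rel["rel_delta"] > rel[-1]))
})

test_that("EEG sampling below twice the gamma edge is rejected", {
  expect_error(cohort_config(list(condition(20, 1.4)), eeg_rate = 150), "eeg_rate")
})

test_that("photometry transient peaks at the analytic kernel offset", {
  cfg <- quiet_config()
  cfg$photometry$noise_sd <- 0
  cfg$photometry$drift_per_s <- 0
  ev <- c(RORR = 100)
  tr <- simulate_photometry(cfg, ev, seed = 1, span_s = c(0, 300))
  pk_expect <- photometry_kernel_peak(cfg$photometry$rise_s, cfg$photometry$decay_s)
  pk_obs <- tr$times[which.max(tr$f_raw)] - 100
  expect_equal(pk_obs, pk_expect, tolerance = 1.5 / cfg$photometry$rate)
  # amplitude zero: flat baseline
  cfg$photometry$amplitude <- 0
  tr0 <- simulate_photometry(cfg, ev, seed = 1, span_s = c(0, 300))
  expect_lt(diff(range(tr0$f_raw)), 1e-9)
})

test_that("photometry rejects empty events and bad time constants", {
  cfg <- quiet_config()
  expect_error(simulate_photometry(cfg, numeric()), "non-empty")
  cfg$photometry$rise_s <- -1
  expect_error(simulate_photometry(cfg, c(LORR = 10)), "time constants")
})

test_that("cohorts are deterministic and sized by design", {
  cfg <- cohort_config(list(condition(20, 1.4, group_label = "cold"),
                            condition(32, 1.4, group_label = "warm")),
                       n_per_group = 3, seed = 11,
                       eeg_span_min = c(-1, 2), temp_span_min = c(-10, 40))
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
  expect_length(co1$animals, 6)
  # gate length equals the EEG sample count (ground-truth invariant)
  expect_length(co1$animals[[1]]$gate, length(co1$animals[[1]]$eeg$samples))
  # duplicate labels rejected
  expect_error(cohort_config(list(condition(20, 1.4), condition(20, 1.4))),
               "duplicate")
})

test_that("per-animal seeds are order-independent", {
  expect_identical(derive_seed(5, 17), derive_seed(5, 17))
  expect_false(derive_seed(5, 17) == derive_seed(5, 18))
  expect_false(derive_seed(5, 17) == derive_seed(6, 17))
  s <- vapply(1:100, function(i) derive_seed(1, i), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 1 & s < 2^31))
})
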