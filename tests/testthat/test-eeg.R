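# EEG analysis: band powers, suppression detection, burst-suppression ratio.

make_rec <- function(x, rate = 250, t0 = 0, markers = numeric())
  eeg_recording(x, rate, t0 = t0, markers = markers)

test_that("a pure delta-band sinusoid carries ~all relative power in delta", {
  rate <- 250
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  x <- 50 * sin(2 * pi * 2.5 * t) + 1e-3 * sin(2 * pi * 40 * t)
  bp <- compute_band_powers(make_rec(x, rate), epoch_len = 30)
  expect_true(all(bp$rel_delta >= 0.99))
})

test_that("two equal tones split relative power 50/50 (Parseval)", {
  rate <- 250
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  a <- 30
  x <- a * sin(2 * pi * 2.5 * t) + a * sin(2 * pi * 30 * t)
  bp <- compute_band_powers(make_rec(x, rate), epoch_len = 30)
  expect_equal(mean(bp$rel_delta), 0.5, tolerance = 0.02)
  expect_equal(mean(bp$rel_gamma), 0.5, tolerance = 0.02)
  # Parseval: total band power ~ time-domain variance (two tones: a^2)
  expect_equal(mean(bp$total), a^2, tolerance = 0.02 * a^2)
})

test_that("band powers respect invariants on stationary signals", {
  set.seed(4)
  rate <- 250
  x <- rnorm(rate * 60)
  bp <- compute_band_powers(make_rec(x, rate), epoch_len = 30)
  rels <- bp[, c("rel_delta", "rel_theta", "rel_alpha", "rel_beta", "rel_gamma")]
  expect_true(all(rels >= 0 & rels <= 1))
  expect_true(all(rowSums(rels) <= 1 + 1e-12))  # band gaps leave headroom
  for (b in c("delta", "theta", "alpha", "beta", "gamma"))
    expect_true(all(bp$total >= bp[[b]] - 1e-12))
})

test_that("band-power input validation", {
  rec <- make_rec(rnorm(250 * 10))
  expect_error(compute_band_powers(rec, epoch_len = 2), ">= 4")
  expect_error(compute_band_powers(rec, epoch_len = 60), "longer than record")
  expect_error(eeg_recording(c(1, NA, 3), 250), "finite")
})

test_that("all-zero record yields one suppression interval spanning it", {
  rec <- make_rec(numeric(250 * 10))
  iv <- detect_suppressions(rec, threshold_uv = 5)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 10)
})

test_that("square-envelope suppressions are recovered within 50 ms", {
  rate <- 500
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  env <- ifelse(floor(t) %% 2 == 0, 50, 0.5)   # 1-s high / 1-s near-zero
  set.seed(9)
  x <- env * sin(2 * pi * 10 * t + runif(1))
  rec <- make_rec(x, rate)
  iv <- detect_suppressions(rec, threshold_uv = 5, min_dur = 0.5)
  truth_starts <- seq(1, 19, by = 2)
  expect_equal(nrow(iv), length(truth_starts))
  expect_lt(max(abs(iv$start - truth_starts)), 0.05 + 1e-9)
  expect_lt(max(abs(iv$end - (truth_starts + 1))), 0.05 + 1e-9)
})

test_that("detector agrees with the generator's gate on >= 95% of samples", {
  cfg <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(-1, 5), iso_start_min = 0, iso_stop_min = 5,
                       suppression_map = list(t_half = 29, steepness = 0.2,
                                              max_fraction = 0.8))
  tr <- constant_temp_trace(28)
  ee <- simulate_eeg(cfg, condition(20, 1.4), tr, seed = 2)
  rec <- ee$recording
  iv <- detect_suppressions(rec)
  tt <- rec$t0 + (seq_along(rec$samples) - 1) / rec$rate
  mask <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(iv))) mask[tt >= iv$start[i] & tt < iv$end[i]] <- TRUE
  sel <- tt >= 0 & tt < 300
  expect_gte(mean(mask[sel] == !ee$gate[sel]), 0.95)
})

test_that("BSR is invariant to amplitude rescaling in adaptive mode", {
  cfg <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(-1, 4), iso_start_min = 0, iso_stop_min = 4)
  tr <- constant_temp_trace(27)
  ee <- simulate_eeg(cfg, condition(20, 1.4), tr, seed = 3)
  rec <- ee$recording
  rec10 <- eeg_recording(rec$samples * 10, rec$rate, rec$t0, rec$markers)
  b1 <- attr(compute_bsr(detect_suppressions(rec), rec), "overall")
  b2 <- attr(compute_bsr(detect_suppressions(rec10), rec10), "overall")
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("BSR arithmetic: bins, overall, and window accounting", {
  # 30 suppressed seconds of a 60-s bin -> 50%
  iv <- structure(data.frame(start = 10, end = 40),
                  class = c("suppression_intervals", "data.frame"))
  rec <- make_rec(rnorm(250 * 120), 250)
  bsr <- compute_bsr(iv, rec, bin_len = 60, window = c(0, 120))
  expect_equal(bsr$bsr_pct, c(50, 0))
  expect_equal(attr(bsr, "overall"), 25)
  # per-bin mean equals overall for equal bins
  expect_equal(mean(bsr$bsr_pct), attr(bsr, "overall"))
  # fully suppressed record -> 100% every bin
  iv_full <- structure(data.frame(start = 0, end = 120),
                       class = c("suppression_intervals", "data.frame"))
  bsr_full <- compute_bsr(iv_full, rec, window = c(0, 120))
  expect_true(all(bsr_full$bsr_pct == 100))
})

test_that("overall BSR tracks the generator's gate fraction", {
  cfg <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                       eeg_span_min = c(-1, 11), iso_start_min = 0, iso_stop_min = 11,
                       suppression_map = list(t_half = 29, steepness = 0.2,
                                              max_fraction = 0.7))
  tr <- constant_temp_trace(29)   # p = 0.35 at the midpoint
  ee <- simulate_eeg(cfg, condition(20, 1.4), tr, seed = 4)
  rec <- ee$recording
  bsr <- compute_bsr(detect_suppressions(rec), rec, window = c(0, 600))
  gate_pct <- 100 * mean(!ee$gate[rec$t0 + (seq_along(rec$samples) - 1) / rec$rate >= 0 &
                                  rec$t0 + (seq_along(rec$samples) - 1) / rec$rate < 600])
  expect_equal(attr(bsr, "overall"), gate_pct, tolerance = 5)
  expect_equal(attr(bsr, "overall"), 35, tolerance = 9)  # 3 SE band
})

test_that("delta relative power increases with the generator's delta weight", {
  cfg_base <- cohort_config(list(condition(20, 1.4)), seed = 1, eeg_rate = 250,
                            eeg_span_min = c(0, 2))
  tr <- constant_temp_trace(30)
  rel_for <- function(dw) {
    rest <- (1 - dw) / 4
    cfg <- cfg_base
    cfg$band_weight_profiles <- function(cond)
      c(delta = dw, theta = rest, alpha = rest, beta = rest, gamma = rest)
    ee <- simulate_eeg(cfg, condition(20, 1.4), tr, seed = 7, gating = FALSE)
    mean(compute_band_powers(ee$recording, epoch_len = 30)$rel_delta)
  }
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8), rel_for, numeric(1))
  expect_true(all(diff(vals) > 0))
})
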