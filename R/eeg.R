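# EEG analysis: relative band powers and the burst-suppression ratio.

#' Construct an EEG recording object
#'
#' @param samples Numeric voltage series (uV), finite.
#' @param rate Sampling rate (Hz); must exceed twice the highest band edge
#'   (minimum 120 Hz).
#' @param t0 Time of the first sample, seconds relative to isoflurane start.
#' @param markers Named numeric vector of event times (s), e.g. iso_start,
#'   iso_stop.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, t0 = 0, markers = numeric()) {
  if (!is.numeric(samples) || !length(samples))
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (rate < 120) stop("rate must be >= 120 Hz (twice the highest band edge)",
                       call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d samples at %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' Standard EEG frequency-band table
#'
#' Closed intervals delta 1-4, theta 5-8, alpha 9-12, beta 13-25, gamma
#' 26-60 Hz, and total 1-60 Hz. The gaps between bands (4-5, 8-9, 12-13,
#' 25-26 Hz) are intentional: relative powers are each band over the 1-60 Hz
#' total, so the five band fractions need not sum to 1.
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma", "total"),
             lo = c(1, 5, 9, 13, 26, 1),
             hi = c(4, 8, 12, 25, 60, 60),
             stringsAsFactors = FALSE)
}

# Welch PSD: averaged modified periodogram with Hann taper. Returns a
# one-sided density (power per Hz) on a grid of step rate/nper.
.welch_psd <- function(x, rate, seg_sec = 4, overlap = 0.5) {
  nper <- round(seg_sec * rate)
  n <- length(x)
  if (n < nper) stop("segment longer than signal", call. = FALSE)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  k <- seq_len(nper) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / (nper - 1))     # Hann
  norm <- sum(w^2) * rate
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / norm
    if (nper %% 2 == 0) P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    else P[2:nf] <- 2 * P[2:nf]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1L) * rate / nper, psd = acc / length(starts))
}

#' Per-epoch absolute and relative band powers
#'
#' Splits the record into consecutive epochs and, per epoch, integrates a
#' Welch averaged periodogram (4-s Hann segments, 50% overlap by default)
#' over each closed band interval. Relative power is the band's absolute
#' power divided by the 1-60 Hz total.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len Epoch length in seconds (>= 4, <= record duration).
#' @param bands Band table as from [eeg_bands()].
#' @param seg_sec,overlap Welch segment length (s) and fractional overlap.
#' @return A `band_power_summary` data.frame: one row per epoch with
#'   `epoch_start`/`epoch_end` (s), absolute powers (uV^2) per band and
#'   `total`, and `rel_*` fractions.
#' @export
compute_band_powers <- function(rec, epoch_len = 30, bands = eeg_bands(),
                                seg_sec = 4, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (anyNA(rec$samples)) stop("NaN in samples", call. = FALSE)
  if (epoch_len < 4) stop("epoch_len must be >= 4 s", call. = FALSE)
  dur <- length(rec$samples) / rec$rate
  if (epoch_len > dur) stop("epoch longer than record", call. = FALSE)
  nper_epoch <- round(epoch_len * rec$rate)
  n_epochs <- floor(length(rec$samples) / nper_epoch)
  band_rows <- bands[bands$band != "total", ]
  total_row <- bands[bands$band == "total", ]
  out <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    i0 <- (e - 1L) * nper_epoch + 1L
    seg <- rec$samples[i0:(i0 + nper_epoch - 1L)]
    ps <- .welch_psd(seg, rec$rate, seg_sec = min(seg_sec, epoch_len), overlap = overlap)
    df_hz <- ps$freq[2] - ps$freq[1]
    bp <- vapply(seq_len(nrow(band_rows)), function(b) {
      sel <- ps$freq >= band_rows$lo[b] & ps$freq <= band_rows$hi[b]
      sum(ps$psd[sel]) * df_hz
    }, numeric(1))
    names(bp) <- band_rows$band
    tot <- sum(ps$psd[ps$freq >= total_row$lo & ps$freq <= total_row$hi]) * df_hz
    row <- data.frame(epoch_start = rec$t0 + (i0 - 1L) / rec$rate,
                      epoch_end = rec$t0 + (i0 - 1L + nper_epoch) / rec$rate)
    for (b in names(bp)) row[[b]] <- bp[[b]]
    row$total <- tot
    for (b in names(bp)) row[[paste0("rel_", b)]] <- if (tot > 0) bp[[b]] / tot else NA_real_
    out[[e]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("band_power_summary", "data.frame")
  res
}

# Moving RMS envelope, window in seconds, centered; edges padded with the
# nearest interior value.
.moving_rms <- function(x, rate, window_s) {
  w <- max(1L, round(window_s * rate))
  kern <- rep(1 / w, w)
  m <- stats::filter(x^2, kern, sides = 2)
  m <- as.numeric(m)
  # fill edge NAs
  ok <- which(!is.na(m))
  if (!length(ok)) return(sqrt(mean(x^2)) + numeric(length(x)))
  m[seq_len(ok[1] - 1)] <- m[ok[1]]
  m[seq.int(ok[length(ok)] + 1L, length.out = length(m) - ok[length(ok)])] <- m[ok[length(ok)]]
  sqrt(pmax(m, 0))
}

#' Detect suppression intervals in an EEG record
#'
#' A sample is suppressed when the moving-RMS envelope (0.1-s window) stays
#' below threshold; runs shorter than `min_dur` are discarded. The threshold
#' is either absolute (`threshold_uv`) or adaptive: `threshold_frac` times
#' the RMS of an awake baseline window (default: all samples before the
#' `iso_start` marker). The adaptive mode makes the detector, and therefore
#' the burst-suppression ratio, invariant to overall gain.
#'
#' @param rec An [eeg_recording()].
#' @param threshold_uv Absolute envelope threshold (uV), or NULL for adaptive.
#' @param threshold_frac Adaptive threshold as a fraction of awake RMS.
#' @param baseline Baseline window c(start, end) in seconds (record time);
#'   default everything before the `iso_start` marker.
#' @param min_dur Minimum suppression duration (s), >= 2 samples.
#' @param rms_window Envelope RMS window (s).
#' @return A `suppression_intervals` data.frame with columns `start`, `end`
#'   (s, closed-open), plus detector settings as attributes.
#' @export
detect_suppressions <- function(rec, threshold_uv = NULL, threshold_frac = 0.25,
                                baseline = NULL, min_dur = 0.5, rms_window = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (min_dur < 2 / rec$rate) stop("min_dur must be >= 2 samples", call. = FALSE)
  times <- rec$t0 + (seq_along(rec$samples) - 1L) / rec$rate
  if (is.null(threshold_uv)) {
    if (is.null(baseline)) {
      if (!("iso_start" %in% names(rec$markers)))
        stop("adaptive threshold needs a baseline window or an iso_start marker",
             call. = FALSE)
      baseline <- c(rec$t0, rec$markers[["iso_start"]])
    }
    sel <- times >= baseline[1] & times < baseline[2]
    if (sum(sel) < rec$rate)
      stop("baseline window shorter than 1 s", call. = FALSE)
    thr <- threshold_frac * sqrt(mean(rec$samples[sel]^2))
  } else {
    thr <- threshold_uv
  }
  if (thr <= 0) stop("threshold must be > 0", call. = FALSE)
  env <- .moving_rms(rec$samples, rec$rate, rms_window)
  mask <- env < thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # the centered RMS window blurs each boundary by rms_window/2, shortening
  # sub-threshold runs by ~rms_window: compensate in the run-length gate and
  # re-expand the detected intervals by half a window per side
  eff_min <- max(2 / rec$rate, min_dur - rms_window)
  keep <- r$values & (r$lengths >= round(eff_min * rec$rate))
  s_s <- rec$t0 + (starts[keep] - 1L) / rec$rate - rms_window / 2
  e_s <- rec$t0 + ends[keep] / rec$rate + rms_window / 2
  rec_end <- rec$t0 + length(rec$samples) / rec$rate
  s_s <- pmax(s_s, rec$t0)
  e_s <- pmin(e_s, rec_end)
  # merge intervals that touch after expansion
  if (length(s_s) > 1) {
    ms <- s_s[1]; me <- e_s[1]; out_s <- numeric(); out_e <- numeric()
    for (i in 2:length(s_s)) {
      if (s_s[i] <= me + 1e-12) me <- max(me, e_s[i])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s_s[i]; me <- e_s[i] }
    }
    s_s <- c(out_s, ms); e_s <- c(out_e, me)
  }
  iv <- data.frame(start = s_s, end = e_s)
  attr(iv, "threshold_uv") <- thr
  attr(iv, "min_dur") <- min_dur
  attr(iv, "rms_window") <- rms_window
  class(iv) <- c("suppression_intervals", "data.frame")
  iv
}

#' Burst-suppression ratio per time bin and overall
#'
#' BSR is the suppressed duration divided by the total duration, as a
#' percentage: per bin (default 1-min bins) and overall across the analysis
#' window. The overall value is the duration-weighted mean of the bins.
#'
#' @param intervals A [detect_suppressions()] result.
#' @param rec The corresponding [eeg_recording()].
#' @param bin_len Bin length (s), default 60.
#' @param window Analysis window c(start, end) in seconds; default the
#'   maintenance window: `iso_start` marker (or record start) to +30 min,
#'   clipped to the record.
#' @return A `bsr_trace` data.frame with `bin_start`, `bin_end` (s),
#'   `bsr_pct`; the overall BSR (%) is in `attr(, "overall")`.
#' @export
compute_bsr <- function(intervals, rec, bin_len = 60, window = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(rec$samples)) stop("empty record", call. = FALSE)
  rec_end <- rec$t0 + length(rec$samples) / rec$rate
  if (is.null(window)) {
    w0 <- if ("iso_start" %in% names(rec$markers)) rec$markers[["iso_start"]] else rec$t0
    window <- c(max(w0, rec$t0), min(w0 + 1800, rec_end))
  }
  if (window[2] <= window[1]) stop("empty analysis window", call. = FALSE)
  overlap_len <- function(a0, a1) {
    if (!nrow(intervals)) return(0)
    sum(pmax(0, pmin(intervals$end, a1) - pmax(intervals$start, a0)))
  }
  n_bins <- max(1L, ceiling((window[2] - window[1]) / bin_len - 1e-9))
  bin_starts <- window[1] + bin_len * (seq_len(n_bins) - 1L)
  bin_ends <- pmin(bin_starts + bin_len, window[2])
  bsr <- vapply(seq_along(bin_starts), function(i)
    100 * overlap_len(bin_starts[i], bin_ends[i]) / (bin_ends[i] - bin_starts[i]),
    numeric(1))
  out <- data.frame(bin_start = bin_starts, bin_end = bin_ends, bsr_pct = bsr)
  attr(out, "overall") <- 100 * overlap_len(window[1], window[2]) /
    (window[2] - window[1])
  attr(out, "window") <- window
  class(out) <- c("bsr_trace", "data.frame")
  out
}
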