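# Fiber-photometry processing: dF/F, Z-score, peri-event alignment, peaks.

#' Construct a photometry trace object
#'
#' @param times Uniformly spaced sample times (s).
#' @param f_raw Raw fluorescence (arbitrary units), finite.
#' @param markers Named numeric event times (s), e.g. LORR, RORR.
#' @return An object of class `photometry_trace`.
#' @export
photometry_trace <- function(times, f_raw, markers = numeric()) {
  stopifnot(length(times) == length(f_raw), length(times) >= 2)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("photometry sampling must be uniform", call. = FALSE)
  if (anyNA(f_raw) || any(!is.finite(f_raw)))
    stop("f_raw must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), f_raw = as.numeric(f_raw),
                 markers = markers),
            class = "photometry_trace")
}

.trace_rate <- function(trace) 1 / (trace$times[2] - trace$times[1])

.baseline_stats <- function(trace, baseline) {
  sel <- trace$times >= baseline[1] & trace$times <= baseline[2]
  if (sum(sel) < 2) stop("baseline window contains fewer than 2 samples", call. = FALSE)
  vals <- trace$f_raw[sel]
  list(mu = mean(vals), sigma = stats::sd(vals), n = sum(sel))
}

#' Fractional fluorescence change (dF/F)
#'
#' dF/F(t) = (F(t) - F0) / F0 with F0 the mean fluorescence over the
#' baseline window (by convention the 50 s immediately preceding the
#' alignment event: isoflurane start for induction analyses, isoflurane
#' cessation for emergence analyses).
#'
#' @param trace A [photometry_trace()].
#' @param baseline c(start, end) of the baseline window (s).
#' @return A `dff_trace`: list with `times`, `values` (dimensionless),
#'   `baseline`, `mu`, `sigma`, `markers`.
#' @export
compute_dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "photometry_trace"), length(baseline) == 2)
  bs <- .baseline_stats(trace, baseline)
  if (bs$mu <= 0) stop("baseline mean must be > 0 for dF/F", call. = FALSE)
  structure(list(times = trace$times, values = (trace$f_raw - bs$mu) / bs$mu,
                 baseline = baseline, mu = bs$mu, sigma = bs$sigma,
                 markers = trace$markers),
            class = "dff_trace")
}

#' Baseline Z-score of a photometry trace
#'
#' Z(t) = (F(t) - mu) / sigma with mu, sigma the mean and standard deviation
#' of the baseline window. Invariant under adding a constant to the trace
#' and under positive rescaling.
#'
#' @inheritParams compute_dff
#' @return A `z_trace`: list with `times`, `values` (SD units), `baseline`,
#'   `mu`, `sigma`, `markers`.
#' @export
compute_zscore <- function(trace, baseline) {
  stopifnot(inherits(trace, "photometry_trace"), length(baseline) == 2)
  bs <- .baseline_stats(trace, baseline)
  if (bs$sigma <= 0) stop("baseline sd must be > 0 for Z-score", call. = FALSE)
  structure(list(times = trace$times, values = (trace$f_raw - bs$mu) / bs$sigma,
                 baseline = baseline, mu = bs$mu, sigma = bs$sigma,
                 markers = trace$markers),
            class = "z_trace")
}

#' Align Z-scored trials around events
#'
#' Extracts one window per event, `pre` seconds before to `post` seconds
#' after, endpoints inclusive, so each row has round((pre+post)*rate) + 1
#' samples and the column at offset 0 is the event sample (nearest-sample
#' alignment). Events without full window coverage are dropped with a
#' warning.
#'
#' @param ztrace A [compute_zscore()] (or [compute_dff()]) result.
#' @param events Numeric event times (s), non-empty; names become trial
#'   labels.
#' @param pre,post Window extent before/after the event (s).
#' @return A `peri_event_tensor`: matrix (trials x time) with attribute
#'   `offsets` (s relative to the event).
#' @export
align_peri_event <- function(ztrace, events, pre = 50, post = 300) {
  if (!length(events)) stop("empty event list", call. = FALSE)
  rate <- 1 / (ztrace$times[2] - ztrace$times[1])
  npre <- round(pre * rate)
  npost <- round(post * rate)
  rows <- list()
  kept <- character()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    i0 <- nearest_index(ztrace$times, ev)
    lo <- i0 - npre
    hi <- i0 + npost
    if (lo < 1 || hi > length(ztrace$values)) {
      warning(sprintf("event at %.2f s lacks full window coverage; trial dropped", ev))
      next
    }
    rows[[length(rows) + 1L]] <- ztrace$values[lo:hi]
    kept <- c(kept, if (!is.null(names(events)) && nzchar(names(events)[i]))
      names(events)[i] else sprintf("trial%d", i))
  }
  if (!length(rows)) stop("no event had full window coverage", call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- kept
  attr(m, "offsets") <- seq(-npre, npost) / rate
  attr(m, "event_times") <- as.numeric(events)
  class(m) <- c("peri_event_tensor", class(m))
  m
}

#' Per-trial peak statistics of a peri-event tensor
#'
#' Maximum value and its time (relative to the event) within an explicit
#' search window; ties are broken by the earliest time.
#'
#' @param tensor An [align_peri_event()] result.
#' @param search c(start, end) search window (s relative to the event),
#'   within the tensor's offsets.
#' @return A data.frame with `trial`, `peak_z`, `peak_time_s`.
#' @export
peak_stats <- function(tensor, search) {
  offs <- attr(tensor, "offsets")
  stopifnot(length(search) == 2, search[1] <= search[2])
  tol <- (offs[2] - offs[1]) / 2        # half a sample of slack
  if (search[1] < min(offs) - tol || search[2] > max(offs) + tol)
    stop("search window outside tensor window", call. = FALSE)
  sel <- offs >= search[1] & offs <= search[2]
  out <- lapply(seq_len(nrow(tensor)), function(r) {
    v <- tensor[r, sel]
    if (all(is.na(v))) stop("all-NaN trial row", call. = FALSE)
    j <- which.max(v)                 # first maximum = earliest tie
    data.frame(trial = rownames(tensor)[r], peak_z = v[j],
               peak_time_s = offs[sel][j], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
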