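# Cohort statistics: righting-reflex latencies, per-animal summaries,
# two-group comparisons.

#' Extract LORR and RORR latencies from a righting-test flip log
#'
#' LORR is the time of the first failed righting at or after isoflurane
#' start, minus the start time; RORR is the time of the first successful
#' righting at or after isoflurane cessation, minus the cessation time.
#' Missing events raise an error rather than silently truncating.
#'
#' @param log Data.frame with columns `time_s` and `outcome`
#'   ("success"/"fail"), one row per cage flip (nominally every 15 s).
#' @param iso_start,iso_stop Isoflurane start/stop times (s).
#' @param rule "first" (default) scores LORR at the first failed flip;
#'   "two_consecutive" requires two consecutive failures and scores the
#'   first of the pair.
#' @return Named numeric vector c(lorr = ..., rorr = ...) in seconds.
#' @export
extract_lorr_rorr <- function(log, iso_start, iso_stop,
                              rule = c("first", "two_consecutive")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(log), all(c("time_s", "outcome") %in% names(log)))
  if (!all(log$outcome %in% c("success", "fail")))
    stop("outcome must be 'success' or 'fail'", call. = FALSE)
  log <- log[order(log$time_s), ]
  post_start <- log[log$time_s >= iso_start, ]
  fails <- which(post_start$outcome == "fail")
  if (rule == "two_consecutive" && length(fails) > 1)
    fails <- fails[which(diff(fails) == 1L)]    # first flip of each failed pair
  if (!length(fails)) stop("no failed righting after isoflurane start", call. = FALSE)
  lorr <- post_start$time_s[fails[1L]] - iso_start
  post_stop <- log[log$time_s >= iso_stop, ]
  succ <- which(post_stop$outcome == "success")
  if (!length(succ)) stop("no successful righting after isoflurane cessation",
                          call. = FALSE)
  rorr <- post_stop$time_s[succ[1L]] - iso_stop
  c(lorr = lorr, rorr = rorr)
}

# Core temperature at a target minute: nearest logged sample, earlier on ties.
.t_core_at_min <- function(trace, t_min) {
  trace$values[nearest_index(trace$times, t_min)]
}

#' Summarize one animal's recordings
#'
#' Assembles the per-animal quantities the group analyses use: core
#' temperature at t = -30, 0, 32 min and at the RORR moment (nearest 2-min
#' sample, ties to the earlier sample), LORR/RORR latencies, overall
#' burst-suppression ratio over the maintenance window (0-30 min), mean
#' relative band powers over maintenance and recovery (cessation to RORR)
#' windows, and the photometry peak Z around emergence. Missing modalities
#' yield NA fields.
#'
#' @param bundle List with elements `temperature` (a `temperature_trace`),
#'   and optionally `eeg` (an `eeg_recording`), `righting` (flip log),
#'   `photometry` (a `photometry_trace`), `group`, `id`.
#' @param iso_start_min,iso_stop_min Anesthesia window (min).
#' @param epoch_len Band-power epoch length (s).
#' @param peak_search Photometry peak search window (s after RORR).
#' @return One-row data.frame of summary metrics.
#' @export
summarize_animal <- function(bundle, iso_start_min = 0, iso_stop_min = 32,
                             epoch_len = 30, peak_search = c(0, 60)) {
  stopifnot(inherits(bundle$temperature, "temperature_trace"))
  tr <- bundle$temperature
  iso_start_s <- iso_start_min * 60
  iso_stop_s <- iso_stop_min * 60
  out <- data.frame(
    id = if (!is.null(bundle$id)) bundle$id else NA_character_,
    group = if (!is.null(bundle$group)) bundle$group else NA_character_,
    t_core_m30 = .t_core_at_min(tr, -30),
    t_core_0 = .t_core_at_min(tr, 0),
    t_core_32 = .t_core_at_min(tr, iso_stop_min),
    t_core_rorr = NA_real_,
    lorr_s = NA_real_, rorr_s = NA_real_, bsr_overall = NA_real_,
    stringsAsFactors = FALSE)
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    out[[paste0("rel_", b, "_maint")]] <- NA_real_
    out[[paste0("rel_", b, "_recov")]] <- NA_real_
  }
  out$photo_peak_z <- NA_real_
  out$photo_peak_time_s <- NA_real_

  if (!is.null(bundle$righting)) {
    lr <- extract_lorr_rorr(bundle$righting, iso_start_s, iso_stop_s)
    out$lorr_s <- lr[["lorr"]]
    out$rorr_s <- lr[["rorr"]]
    out$t_core_rorr <- .t_core_at_min(tr, iso_stop_min + lr[["rorr"]] / 60)
  }

  if (!is.null(bundle$eeg)) {
    rec <- bundle$eeg
    iv <- detect_suppressions(rec)
    out$bsr_overall <- attr(compute_bsr(iv, rec,
                                        window = c(iso_start_s, min(iso_start_s + 1800,
                                                                    rec$t0 + length(rec$samples) / rec$rate))),
                            "overall")
    bp <- compute_band_powers(rec, epoch_len = epoch_len)
    maint <- bp[bp$epoch_start >= iso_start_s & bp$epoch_end <= iso_start_s + 1800, ]
    for (b in c("delta", "theta", "alpha", "beta", "gamma"))
      if (nrow(maint)) out[[paste0("rel_", b, "_maint")]] <- mean(maint[[paste0("rel_", b)]])
    if (!is.na(out$rorr_s)) {
      recov <- bp[bp$epoch_start >= iso_stop_s &
                  bp$epoch_end <= iso_stop_s + max(out$rorr_s, epoch_len), ]
      for (b in c("delta", "theta", "alpha", "beta", "gamma"))
        if (nrow(recov)) out[[paste0("rel_", b, "_recov")]] <- mean(recov[[paste0("rel_", b)]])
    }
  }

  if (!is.null(bundle$photometry) && !is.na(out$rorr_s)) {
    ph <- bundle$photometry
    rorr_abs <- iso_stop_s + out$rorr_s
    z <- tryCatch(compute_zscore(ph, c(iso_stop_s - 50, iso_stop_s)),
                  error = function(e) NULL)
    if (!is.null(z)) {
      tens <- tryCatch(
        suppressWarnings(align_peri_event(z, c(RORR = rorr_abs), pre = 50,
                                          post = max(peak_search[2], 60))),
        error = function(e) NULL)
      if (!is.null(tens)) {
        pk <- peak_stats(tens, peak_search)
        out$photo_peak_z <- pk$peak_z[1]
        out$photo_peak_time_s <- pk$peak_time_s[1]
      }
    }
  }
  out
}

#' Summarize every animal of a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [summarize_animal()].
#' @return Data.frame with one row per animal.
#' @export
summarize_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  iso_start <- cohort$config$iso_start_min
  iso_stop <- cohort$config$iso_stop_min
  do.call(rbind, lapply(cohort$animals, summarize_animal,
                        iso_start_min = iso_start, iso_stop_min = iso_stop, ...))
}

#' Two-group comparison of a summary metric
#'
#' Two-sample t test (pooled variance for unpaired, matching the common
#' spreadsheet-package default; paired on matched ordering when
#' `paired = TRUE`) with mean +/- SEM per group and an optional Bonferroni
#' family correction p_adj = min(1, p * family_size). Zero variance in both
#' groups with equal means yields t = 0, p = 1 by convention.
#'
#' @param summaries Data.frame with a `group` column (e.g. from
#'   [summarize_cohort()]).
#' @param metric Column name to compare.
#' @param groups Character vector of the two group labels; default the two
#'   present.
#' @param paired Paired test (requires equal n, rows matched by order).
#' @param family_size Bonferroni family size (default 1 = no correction).
#' @return A `group_comparison`: list with per-group `mean`, `sem`, `n`,
#'   the test name, `t`, `df`, `p`, `p_adj`.
#' @export
compare_groups <- function(summaries, metric, groups = NULL, paired = FALSE,
                           family_size = 1) {
  stopifnot(is.data.frame(summaries), metric %in% names(summaries),
            "group" %in% names(summaries))
  if (is.null(groups)) {
    groups <- unique(summaries$group)
    if (length(groups) != 2)
      stop("summaries contain ", length(groups),
           " groups; specify which two to compare", call. = FALSE)
  }
  a <- summaries[summaries$group == groups[1], metric]
  b <- summaries[summaries$group == groups[2], metric]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired test requires equal group sizes", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (paired) {
    d <- a - b
    if (stats::var(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- stats::t.test(a, b, paired = TRUE)
    test_name <- "paired t"
  } else {
    if (va == 0 && vb == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else tt <- stats::t.test(a, b, var.equal = TRUE)
    test_name <- "unpaired t (pooled variance)"
  }
  p <- tt$p.value
  structure(list(groups = groups, metric = metric,
                 mean = c(mean(a), mean(b)),
                 sem = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
                 n = c(length(a), length(b)),
                 test = test_name,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = p, p_adj = min(1, p * family_size)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d)\n",
              x$metric, x$test,
              x$groups[1], x$mean[1], x$sem[1], x$n[1],
              x$groups[2], x$mean[2], x$sem[2], x$n[2]))
  cat(sprintf("  t(%g) = %.4g, p = %.4g, Bonferroni-adjusted p = %.4g\n",
              x$df, x$t, x$p, x$p_adj))
  invisible(x)
}
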