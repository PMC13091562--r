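# File I/O: CSV readers/writers for every modality and cohort directory
# trees. All CSV files are comma-separated UTF-8 with `.` decimals, times in
# seconds (minutes only for temperature logs, which follow the 2-min-cadence
# logger convention), and a header row naming units.

#' Read an EEG recording
#'
#' CSV files must have columns `time_s,uv` with uniform timestamps (relative
#' deviation below 1e-6); the sampling rate is inferred from the time grid.
#' EDF input is not supported by this build; convert to CSV first.
#'
#' @param path File path.
#' @param format "auto" (by extension), "csv" or "edf".
#' @param markers Optional named event times (s) to attach.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf"), markers = numeric()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf")
    stop("EDF input is not supported; export the channel to CSV (time_s,uv)",
         call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "uv") %in% names(d)))
    stop("EEG CSV must have columns time_s,uv", call. = FALSE)
  if (anyNA(d$time_s) || anyNA(d$uv)) stop("missing values in EEG CSV", call. = FALSE)
  dt <- diff(d$time_s)
  bad <- which(abs(dt - dt[1]) > 1e-6 * dt[1])
  if (length(bad))
    stop(sprintf("non-uniform EEG timing: first bad gap after row %d (dt = %g vs %g s)",
                 bad[1] + 1L, dt[bad[1]], dt[1]), call. = FALSE)
  eeg_recording(d$uv, rate = 1 / dt[1], t0 = d$time_s[1], markers = markers)
}

#' Write an EEG recording to CSV
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  times <- rec$t0 + (seq_along(rec$samples) - 1) / rec$rate
  utils::write.csv(data.frame(time_s = times, uv = rec$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a core-temperature log (CSV: time_min,temp_c)
#' @param path File path.
#' @param condition Optional [condition()] to attach.
#' @return A `temperature_trace`.
#' @export
read_temperature <- function(path, condition = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "temp_c") %in% names(d)))
    stop("temperature CSV must have columns time_min,temp_c", call. = FALSE)
  if (is.unsorted(d$time_min, strictly = TRUE))
    stop("temperature times must be strictly increasing", call. = FALSE)
  structure(list(times = d$time_min, values = d$temp_c, condition = condition,
                 baseline = NA_real_, equilibrium = NA_real_),
            class = "temperature_trace")
}

#' Write a core-temperature log
#' @param trace A `temperature_trace`.
#' @param path Output path.
#' @export
write_temperature <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace$times, temp_c = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a photometry trace (CSV: time_s,f_raw)
#' @param path File path.
#' @param markers Optional named event times (s).
#' @return A [photometry_trace()].
#' @export
read_photometry <- function(path, markers = numeric()) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "f_raw") %in% names(d)))
    stop("photometry CSV must have columns time_s,f_raw", call. = FALSE)
  photometry_trace(d$time_s, d$f_raw, markers = markers)
}

#' Write a photometry trace
#' @param trace A [photometry_trace()].
#' @param path Output path.
#' @export
write_photometry <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, f_raw = trace$f_raw),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a righting-test flip log (CSV: time_s,outcome)
#' @param path File path.
#' @return Data.frame with `time_s`, `outcome`.
#' @export
read_righting <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "outcome") %in% names(d)))
    stop("righting CSV must have columns time_s,outcome", call. = FALSE)
  if (!all(d$outcome %in% c("success", "fail")))
    stop("righting outcome must be success/fail", call. = FALSE)
  d
}

#' Write a synthetic cohort as a directory tree
#'
#' Layout: `cohort.yaml` (config echo) plus one subdirectory per animal with
#' `temp.csv`, `eeg.csv`, `photometry.csv`, `righting.csv` and `truth.csv`
#' (generator ground truth: true latencies, gate suppressed fraction,
#' calibrated cessation temperature) for whichever modalities were
#' generated.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  cfg_echo <- cfg[!vapply(cfg, is.function, TRUE)]
  cfg_echo$conditions <- lapply(cfg$conditions, function(cd)
    cd[!vapply(cd, is.null, TRUE)])
  yaml::write_yaml(cfg_echo, file.path(dir, "cohort.yaml"))
  for (a in cohort$animals) {
    adir <- file.path(dir, a$id)
    dir.create(adir, showWarnings = FALSE)
    write_temperature(a$temperature, file.path(adir, "temp.csv"))
    if (!is.null(a$eeg)) write_eeg(a$eeg, file.path(adir, "eeg.csv"))
    if (!is.null(a$photometry))
      write_photometry(a$photometry, file.path(adir, "photometry.csv"))
    if (!is.null(a$righting))
      utils::write.csv(a$righting, file.path(adir, "righting.csv"), row.names = FALSE)
    truth <- data.frame(
      lorr_s = if (!is.null(a$truth)) a$truth$lorr_s else NA_real_,
      rorr_s = if (!is.null(a$truth)) a$truth$rorr_s else NA_real_,
      t_core_cessation = if (!is.null(a$truth)) a$truth$t_core_cessation else NA_real_,
      gate_suppressed_fraction = if (!is.null(a$gate)) mean(!a$gate) else NA_real_)
    utils::write.csv(truth, file.path(adir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `config_echo` (raw YAML) and `animals`, each holding
#'   whichever modality files were present.
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  adirs <- list.dirs(dir, recursive = FALSE)
  iso_start_s <- (if (!is.null(cfg$iso_start_min)) cfg$iso_start_min else 0) * 60
  iso_stop_s <- (if (!is.null(cfg$iso_stop_min)) cfg$iso_stop_min else 32) * 60
  animals <- lapply(adirs, function(adir) {
    a <- list(id = basename(adir))
    a$group <- sub("_a[0-9]+$", "", a$id)
    tf <- file.path(adir, "temp.csv")
    if (file.exists(tf)) a$temperature <- read_temperature(tf)
    ef <- file.path(adir, "eeg.csv")
    if (file.exists(ef))
      a$eeg <- read_eeg(ef, markers = c(iso_start = iso_start_s, iso_stop = iso_stop_s))
    pf <- file.path(adir, "photometry.csv")
    if (file.exists(pf)) a$photometry <- read_photometry(pf)
    rf <- file.path(adir, "righting.csv")
    if (file.exists(rf)) a$righting <- read_righting(rf)
    uf <- file.path(adir, "truth.csv")
    if (file.exists(uf)) a$truth <- as.list(utils::read.csv(uf))
    a
  })
  list(config_echo = cfg, animals = animals)
}
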