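# CSV interchange schemas. All files are comma-separated, '.' decimal,
# UTF-8, with documented headers; times in ms, episode durations in s.

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, col, bad[1]))
    }
    df[[col]] <- v
  }
  df
}

#' Read and write single-lead ECG traces as CSV
#'
#' Schema: `time_ms,voltage_mV`. The sampling rate is recovered from the
#' median sample spacing on read.
#'
#' @param signal An [ecg_signal()].
#' @param path File path.
#' @return `read_ecg()` returns an [ecg_signal()]; `write_ecg()` returns
#'   `path` invisibly.
#' @export
write_ecg <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  df <- data.frame(time_ms = sample_times(signal),
                   voltage_mV = signal$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg
#' @param lead,subject_id,group Labels attached to the signal on read.
#' @export
read_ecg <- function(path, lead = "I", subject_id = NA_character_,
                     group = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_ms", "voltage_mV"), path)
  df <- check_numeric(df, c("time_ms", "voltage_mV"), path)
  if (nrow(df) < 2) stop(sprintf("%s: at least two samples required", path))
  dt <- median(diff(df$time_ms))
  ecg_signal(df$voltage_mV, sampling_rate = 1000 / dt, t0 = df$time_ms[1],
             lead = lead, subject_id = subject_id, group = group)
}

#' Read and write RR tachograms as CSV
#'
#' Schema: `beat_time_ms,rr_ms,included`, one row per interval;
#' `beat_time_ms` is the time of the beat opening the interval.
#'
#' @param rr An [rr_series()].
#' @param path File path.
#' @return `read_tachogram()` returns an [rr_series()].
#' @export
write_tachogram <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  write.csv(as.data.frame(rr), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tachogram
#' @export
read_tachogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("beat_time_ms", "rr_ms", "included"), path)
  df <- check_numeric(df, c("beat_time_ms", "rr_ms"), path)
  n <- nrow(df)
  if (n < 1) stop(sprintf("%s: empty tachogram", path))
  beat_times <- c(df$beat_time_ms, df$beat_time_ms[n] + df$rr_ms[n])
  if (any(abs(diff(df$beat_time_ms) - df$rr_ms[-n]) > 1e-6)) {
    stop(sprintf("%s: rr_ms inconsistent with beat_time_ms spacing", path))
  }
  rr_series(beat_times, included = as.logical(df$included))
}

#' Read and write stimulation logs as CSV
#'
#' The event schema is `time,kind,chamber,label,maneuver_id,maneuver_type,
#' drive_cl,coupling`; the executed maneuver roster is written alongside
#' (suffix `.protocol.csv`) because the S1/S2 tissue assignment is not
#' recoverable from events alone.
#'
#' @param log A `stim_log`.
#' @param path Events CSV path; the protocol file is derived from it.
#' @return `read_stimlog()` returns a `stim_log`.
#' @export
write_stimlog <- function(log, path) {
  stopifnot(inherits(log, "stim_log"))
  write.csv(as.data.frame(log$events), path, row.names = FALSE)
  write.csv(as.data.frame(log$protocol), protocol_path(path),
            row.names = FALSE)
  invisible(path)
}

protocol_path <- function(path) sub("(\\.csv)?$", ".protocol.csv", path)

#' @rdname write_stimlog
#' @export
read_stimlog <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(ev, c("time", "kind", "chamber", "label", "maneuver_id",
                      "maneuver_type", "drive_cl", "coupling"), path)
  ev <- check_numeric(ev, c("time", "drive_cl", "coupling"), path)
  pp <- protocol_path(path)
  if (!file.exists(pp)) {
    stop(sprintf("%s: protocol file %s not found", path, pp))
  }
  prot <- read.csv(pp, stringsAsFactors = FALSE)
  check_columns(prot, c("type", "chamber", "drive_cl", "cl", "coupling",
                        "tissue", "burst_s", "maneuver_id"), pp)
  prot <- tibble::as_tibble(prot)
  class(prot) <- c("ep_protocol", class(prot))
  structure(list(events = tibble::as_tibble(ev), protocol = prot),
            class = "stim_log")
}

#' Write per-beat annotations as CSV
#'
#' @param fiducials A `beat_fiducials` table.
#' @param path File path.
#' @export
write_annotations <- function(fiducials, path) {
  write.csv(as.data.frame(fiducials), path, row.names = FALSE)
  invisible(path)
}
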