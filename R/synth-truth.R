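#' Ground-truth beat and fiducial annotations for synthetic ECG
#'
#' A `synth_truth` holds one row per cardiac cycle: an atrial activation
#' time (P onset) with its conduction outcome, or a spontaneous ventricular
#' beat. All surface fiducials (P onset/offset, QRS onset/offset, R peak,
#' T end) are derived from per-beat conduction parameters, so the container
#' is authoritative ground truth for delineation and detector tests.
#'
#' @param x An [rr_series()] providing the atrial activation schedule, or a
#'   numeric vector of beat times in ms.
#' @param pr PR interval (P onset to QRS onset) in ms.
#' @param p_dur P wave duration in ms; must not exceed `pr`.
#' @param qrs_dur QRS duration in ms.
#' @param qt QT interval (QRS onset to T end) in ms; must exceed `qrs_dur`.
#' @param beats_as For a numeric `x`: `"atrial"` (times are P onsets,
#'   default) or `"r_peak"` (times are R peaks; atrial times are derived
#'   backwards and may start before 0).
#' @return Object of class `synth_truth` with a tibble `events` and an
#'   empty injection record.
#' @export
synth_truth <- function(x, pr = 38, p_dur = 11.65, qrs_dur = 10, qt = 30,
                        beats_as = c("atrial", "r_peak")) {
  beats_as <- match.arg(beats_as)
  if (inherits(x, "rr_series")) {
    atrial <- x$beat_times
  } else {
    x <- as.numeric(x)
    if (any(diff(x) <= 0)) stop("beat times must be strictly increasing")
    atrial <- if (beats_as == "atrial") x else x - qrs_dur / 2 - pr
  }
  if (p_dur >= pr) stop("`p_dur` must be smaller than `pr`")
  if (qt <= qrs_dur) stop("`qt` must exceed `qrs_dur`")
  n <- length(atrial)
  events <- tibble::tibble(
    beat = seq_len(n),
    class = rep("sinus", n),
    conducted = rep(TRUE, n),
    atrial_time = atrial,
    vent_time = rep(NA_real_, n),   # filled by rebuild for conducted beats
    pr = rep(pr, n),
    p_dur = rep(p_dur, n),
    qrs_dur = rep(qrs_dur, n),
    qt = rep(qt, n)
  )
  truth <- structure(list(events = events, injections = list()),
                     class = "synth_truth")
  rebuild_fiducials(truth)
}

# derive all fiducial columns from the schedule columns and check ordering
rebuild_fiducials <- function(truth) {
  ev <- truth$events
  sinus <- ev$class != "ventricular"
  conducted <- sinus & ev$conducted
  qrs_onset <- ifelse(conducted, ev$atrial_time + ev$pr,
               ifelse(!sinus, ev$vent_time, NA_real_))
  ev$p_onset <- ifelse(sinus, ev$atrial_time, NA_real_)
  ev$p_offset <- ifelse(sinus, ev$atrial_time + ev$p_dur, NA_real_)
  ev$qrs_onset <- qrs_onset
  ev$qrs_offset <- qrs_onset + ev$qrs_dur
  ev$r_peak <- qrs_onset + ev$qrs_dur / 2
  ev$t_end <- qrs_onset + ev$qt
  has_v <- !is.na(ev$qrs_onset)
  has_p <- !is.na(ev$p_onset)
  bad <- (has_p & has_v & (ev$p_offset > ev$qrs_onset)) |
    (has_p & ev$p_onset >= ev$p_offset) |
    (has_v & (ev$qrs_onset >= ev$qrs_offset | ev$qrs_offset >= ev$t_end))
  if (any(bad, na.rm = TRUE)) {
    stop("fiducial ordering violated (p_onset < p_offset <= qrs_onset < qrs_offset < t_end)")
  }
  ref <- ifelse(has_v, ev$qrs_onset, ev$p_onset)
  if (any(diff(ref) <= 0)) stop("beat reference times must be strictly increasing")
  truth$events <- ev
  truth
}

#' @export
print.synth_truth <- function(x, ...) {
  ev <- x$events
  cat(sprintf(
    "<synth_truth> %d beats (%d sinus conducted, %d non-conducted P, %d ventricular), %d injected disorder(s)\n",
    nrow(ev), sum(ev$class == "sinus" & ev$conducted),
    sum(ev$class == "sinus" & !ev$conducted),
    sum(ev$class == "ventricular"), length(x$injections)
  ))
  invisible(x)
}

#' Ground-truth beat annotations in the delineator's schema
#'
#' Converts a [synth_truth()] into a `beat_fiducials` table so detectors can
#' be run directly against truth (noise-free recoverability checks).
#'
#' @param truth A `synth_truth`.
#' @return A `beat_fiducials` tibble (see [delineate_beats()]).
#' @export
truth_fiducials <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  ev <- truth$events
  out <- tibble::tibble(
    class = ifelse(ev$class == "ventricular", "ventricular",
                   ifelse(ev$conducted, "sinus", "atrial")),
    conducted = ifelse(ev$class == "ventricular", NA, ev$conducted),
    p_onset = ev$p_onset,
    p_offset = ev$p_offset,
    qrs_onset = ev$qrs_onset,
    r_peak = ev$r_peak,
    qrs_offset = ev$qrs_offset,
    t_end = ev$t_end,
    pr = ifelse(!is.na(ev$p_onset) & !is.na(ev$qrs_onset),
                ev$qrs_onset - ev$p_onset, NA_real_)
  )
  class(out) <- c("beat_fiducials", class(out))
  out
}

#' Episode spans of the disorders injected into a truth object
#'
#' @param truth A `synth_truth` after zero or more
#'   [inject_conduction_disorder()] calls.
#' @return Tibble with `kind`, `onset`, `offset` (ms) and `n_beats`;
#'   zero rows when nothing was injected.
#' @export
injected_episodes <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  ev <- truth$events
  rows <- lapply(truth$injections, function(inj) {
    r <- inj$rows
    span <- switch(inj$kind,
      wenckebach = c(ev$p_onset[r[1]], ev$p_offset[r[length(r)]]),
      intermittent_avb3 = c(ev$p_onset[r[1]], ev$p_offset[r[length(r)]]),
      ventricular_run = c(ev$qrs_onset[r[1]], ev$t_end[r[length(r)]]),
      sinus_arrhythmia = c(ev$p_onset[r[1]], ev$t_end[r[length(r)]])
    )
    tibble::tibble(kind = inj$kind, onset = span[1], offset = span[2],
                   n_beats = length(r))
  })
  if (!length(rows)) {
    return(tibble::tibble(kind = character(), onset = numeric(),
                          offset = numeric(), n_beats = integer()))
  }
  do.call(rbind, rows)
}
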