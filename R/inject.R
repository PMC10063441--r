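#' Inject a conduction disorder into a synthetic truth object
#'
#' Rewrites a span of a [synth_truth()] to carry one of the rhythm
#' disorders screened for on the surface ECG, updating ground truth
#' consistently so detectors can be scored by recovery:
#'
#' * `wenckebach`: cycles of `k` conducted beats with monotonically
#'   incrementing PR followed by exactly one non-conducted P
#'   (second-degree AV block, Mobitz type I).
#' * `intermittent_avb3`: runs of two or more consecutive non-conducted
#'   P waves (intermittent third-degree AV block).
#' * `ventricular_run`: at least four consecutive beats reclassified as
#'   spontaneous ventricular activity (no preceding P, broader QRS); runs
#'   shorter than four are rejected because they do not meet the definition
#'   of abnormal ventricular activity.
#' * `sinus_arrhythmia`: RR intervals of a span perturbed by a slow
#'   multiplicative oscillation deep enough to exceed the irregularity
#'   criterion of [detect_sinus_arrhythmia()].
#'
#' @param truth A `synth_truth`.
#' @param disorder One of `"wenckebach"`, `"intermittent_avb3"`,
#'   `"ventricular_run"`, `"sinus_arrhythmia"`.
#' @param start Row index (beat number) at which the disorder starts.
#' @param k Wenckebach: conducted beats per cycle before the dropped P
#'   (at least 2).
#' @param n_cycles Wenckebach: number of consecutive cycles.
#' @param pr_start,pr_increment Wenckebach: PR of the first conducted beat
#'   of each cycle and its per-beat increment, ms.
#' @param run_length `intermittent_avb3`: consecutive dropped P waves per
#'   run (at least 2); `ventricular_run`: run length (at least 4).
#' @param n_runs `intermittent_avb3`: number of runs.
#' @param gap_beats `intermittent_avb3`: conducted beats between runs.
#' @param cl_factor `ventricular_run`: ventricular cycle length as a
#'   fraction of the local atrial cycle length.
#' @param qrs_dur `ventricular_run`: QRS duration of ventricular beats, ms.
#' @param depth,period `sinus_arrhythmia`: modulation depth (fraction of
#'   RR) and period in beats.
#' @param n_beats `sinus_arrhythmia`: span length in beats.
#' @return The modified `synth_truth`; every injected episode is appended
#'   to its injection record (see [injected_episodes()]).
#' @export
inject_conduction_disorder <- function(truth, disorder = c("wenckebach",
                                                           "intermittent_avb3",
                                                           "ventricular_run",
                                                           "sinus_arrhythmia"),
                                       start,
                                       k = 3, n_cycles = 1,
                                       pr_start = NULL, pr_increment = 10,
                                       run_length = 2, n_runs = 1,
                                       gap_beats = 8,
                                       cl_factor = 0.85, qrs_dur = 16,
                                       depth = 0.35, period = 8, n_beats = 40) {
  stopifnot(inherits(truth, "synth_truth"))
  disorder <- match.arg(disorder)
  ev <- truth$events
  n <- nrow(ev)
  check_span <- function(last) {
    if (start < 1 || last > n) stop("disorder span exceeds the record")
    if (any(ev$class[start:last] != "sinus") ||
        !all(ev$conducted[start:last])) {
      stop("disorder span must consist of conducted sinus beats")
    }
  }
  switch(disorder,
    wenckebach = {
      if (k < 2) stop("Wenckebach needs at least 2 conducted beats per cycle")
      if (is.null(pr_start)) pr_start <- ev$pr[start]
      last <- start + n_cycles * (k + 1) - 1
      check_span(last)
      idx <- start
      for (cyc in seq_len(n_cycles)) {
        rows <- idx:(idx + k)            # k conducted + 1 dropped
        prs <- pr_start + pr_increment * (seq_len(k) - 1)
        ev$pr[rows[seq_len(k)]] <- prs
        drop <- rows[k + 1]
        ev$conducted[drop] <- FALSE
        ev$pr[drop] <- NA_real_
        truth$injections <- c(truth$injections,
                              list(list(kind = "wenckebach", rows = rows)))
        idx <- idx + k + 1
      }
    },
    intermittent_avb3 = {
      if (run_length < 2) {
        stop("intermittent third-degree block needs at least 2 consecutive dropped P waves")
      }
      last <- start + n_runs * run_length + (n_runs - 1) * gap_beats - 1
      check_span(last)
      idx <- start
      for (run in seq_len(n_runs)) {
        rows <- idx:(idx + run_length - 1)
        ev$conducted[rows] <- FALSE
        ev$pr[rows] <- NA_real_
        truth$injections <- c(truth$injections,
                              list(list(kind = "intermittent_avb3", rows = rows)))
        idx <- idx + run_length + gap_beats
      }
    },
    ventricular_run = {
      if (run_length < 4) {
        stop("abnormal ventricular activity requires 4 or more consecutive ventricular beats")
      }
      last <- start + run_length - 1
      check_span(last)
      rows <- start:last
      local_cl <- if (start > 1) {
        ev$atrial_time[start] - ev$atrial_time[start - 1]
      } else {
        ev$atrial_time[start + 1] - ev$atrial_time[start]
      }
      v0 <- ev$atrial_time[start]
      vt <- v0 + (seq_along(rows) - 1) * cl_factor * local_cl
      ev$class[rows] <- "ventricular"
      ev$conducted[rows] <- NA
      ev$atrial_time[rows] <- NA_real_
      ev$vent_time[rows] <- vt
      ev$pr[rows] <- NA_real_
      ev$qrs_dur[rows] <- qrs_dur
      truth$injections <- c(truth$injections,
                            list(list(kind = "ventricular_run", rows = rows)))
    },
    sinus_arrhythmia = {
      last <- start + n_beats - 1
      check_span(last)
      rows <- start:last
      at <- ev$atrial_time
      rr <- diff(at)
      j <- seq_len(n_beats - 1)
      rr_idx <- rows[-length(rows)]      # intervals inside the span
      rr[rr_idx] <- rr[rr_idx] * (1 + depth * sin(2 * pi * j / period))
      ev$atrial_time <- at[1] + c(0, cumsum(rr))
      truth$injections <- c(truth$injections,
                            list(list(kind = "sinus_arrhythmia", rows = rows)))
    }
  )
  truth$events <- ev
  rebuild_fiducials(truth)
}
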