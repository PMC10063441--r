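#' Uniformly sampled single-lead ECG trace
#'
#' @param samples Voltage samples in mV.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Time of the first sample in ms (default 0); sample `i` sits at
#'   `t0 + (i - 1) / sampling_rate * 1000` ms.
#' @param lead Lead label (`"I"` or `"II"`).
#' @param subject_id,group Optional labels carried through the pipeline.
#' @return Object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, sampling_rate, t0 = 0, lead = "I",
                       subject_id = NA_character_, group = NA_character_) {
  if (!is.numeric(samples) || !length(samples)) stop("`samples` must be numeric")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         t0 = t0, lead = lead, subject_id = subject_id, group = group),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %.1f s at %g Hz (lead %s, subject %s)\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate,
              x$lead, x$subject_id))
  invisible(x)
}

sample_times <- function(signal) {
  signal$t0 + (seq_along(signal$samples) - 1) / signal$sampling_rate * 1000
}

#' Render a synthetic ECG from ground-truth fiducials
#'
#' Places a stylized murine complex at each beat of a [synth_truth()]:
#' squared-sine (Hann) lobes whose supports are exactly the ground-truth
#' fiducial intervals — a P wave over `[p_onset, p_offset]`, an R wave over
#' `[qrs_onset, qrs_offset]` peaking at `r_peak`, and a T wave over
#' `[qrs_offset, t_end]`. Non-conducted atrial events render a P wave only;
#' ventricular beats render a broader, taller R wave and no P. Morphology
#' is cosmetic; the fiducials are the authoritative truth.
#'
#' @param truth A `synth_truth`.
#' @param sampling_rate Hz, at least 1000 (murine QRS of ~10 ms must be
#'   resolvable); default 2000.
#' @param noise_sd SD of additive white noise in mV (0 = noise free).
#' @param p_amp,r_amp,t_amp,v_amp Wave amplitudes in mV (sinus P/R/T and
#'   ventricular R).
#' @param seed Seed for the noise overlay.
#' @param lead,subject_id,group Labels stored on the signal.
#' @return A list with elements `signal` ([ecg_signal()]) and `truth`.
#' @export
synthesize_ecg <- function(truth, sampling_rate = 2000, noise_sd = 0,
                           p_amp = 0.15, r_amp = 1, t_amp = 0.2, v_amp = 1.2,
                           seed = 1L, lead = "I",
                           subject_id = NA_character_, group = NA_character_) {
  stopifnot(inherits(truth, "synth_truth"))
  if (sampling_rate < 1000) {
    stop("`sampling_rate` must be at least 1000 Hz to resolve a murine QRS")
  }
  ev <- truth$events
  lo <- min(c(ev$p_onset, ev$qrs_onset, 0), na.rm = TRUE) - 5
  hi <- max(c(ev$t_end, ev$p_offset), na.rm = TRUE) + 10
  dt <- 1000 / sampling_rate
  n <- ceiling((hi - lo) / dt) + 1
  tt <- lo + (seq_len(n) - 1) * dt
  x <- numeric(n)
  add_lobe <- function(a, b, amp) {
    i0 <- max(1L, ceiling((a - lo) / dt) + 1L)
    i1 <- min(n, floor((b - lo) / dt) + 1L)
    if (i1 < i0) return(invisible(NULL))
    u <- (tt[i0:i1] - a) / (b - a)
    x[i0:i1] <<- x[i0:i1] + amp * sin(pi * u)^2
    invisible(NULL)
  }
  for (i in seq_len(nrow(ev))) {
    if (!is.na(ev$p_onset[i])) add_lobe(ev$p_onset[i], ev$p_offset[i], p_amp)
    if (!is.na(ev$qrs_onset[i])) {
      amp <- if (ev$class[i] == "ventricular") v_amp else r_amp
      add_lobe(ev$qrs_onset[i], ev$qrs_offset[i], amp)
      add_lobe(ev$qrs_offset[i], ev$t_end[i], t_amp)
    }
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  list(
    signal = ecg_signal(x, sampling_rate, t0 = lo, lead = lead,
                        subject_id = subject_id, group = group),
    truth = truth
  )
}
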