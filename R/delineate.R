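#' Detect R peaks in a single-lead ECG
#'
#' Band-pass (10-300 Hz Butterworth, zero phase) plus squared-derivative
#' energy with an adaptive threshold and a 20 ms refractory lockout —
#' murine heart rates reach 800 bpm, so the lockout must stay well under
#' the shortest credible RR interval.
#'
#' @param signal An [ecg_signal()] of at least 1 s at 500 Hz or more.
#' @param lockout_ms Minimum separation between detections, ms.
#' @param threshold_frac Energy threshold as a fraction of the adaptive
#'   level (99.9th percentile of smoothed energy).
#' @return Numeric vector of R-peak times in ms (empty, with a warning, on
#'   flatline input).
#' @export
detect_r_peaks <- function(signal, lockout_ms = 20, threshold_frac = 0.25) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$sampling_rate
  x <- signal$samples
  if (length(x) < fs) stop("R detection needs at least 1 s of signal")
  if (fs < 500) stop("R detection needs a sampling rate of at least 500 Hz")
  if (diff(range(x)) < 1e-9) {
    warning("flatline input: no beats detected")
    return(numeric(0))
  }
  hi <- min(300, 0.45 * fs)
  bf <- signal::butter(2, c(10, hi) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  en <- c(0, diff(xf))^2
  en_s <- moving_average(en, max(3L, round(0.010 * fs)))
  thr <- threshold_frac * as.numeric(quantile(en_s, 0.999))
  runs <- true_runs(en_s > thr)
  if (!nrow(runs)) {
    warning("no QRS energy above threshold")
    return(numeric(0))
  }
  peaks <- mapply(function(a, b) a - 1L + which.max(en_s[a:b]),
                  runs$start, runs$end)
  # enforce lockout: keep the larger-energy peak of any pair closer than it
  peaks <- sort(peaks)
  lock <- round(lockout_ms / 1000 * fs)
  keep <- rep(TRUE, length(peaks))
  last_pos <- 1L
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - peaks[last_pos] >= lock) {
      last_pos <- i
    } else if (en_s[peaks[i]] > en_s[peaks[last_pos]]) {
      keep[last_pos] <- FALSE
      last_pos <- i
    } else {
      keep[i] <- FALSE
    }
  }
  peaks <- peaks[keep]
  # refine to the local extremum of the band-passed signal
  half <- round(0.010 * fs)
  r_idx <- vapply(peaks, function(p) {
    a <- max(1L, p - half)
    b <- min(length(xf), p + half)
    as.integer(a - 1L + which.max(xf[a:b]))
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  signal$t0 + (r_idx - 1) / fs * 1000
}

idx_at <- function(signal, t_ms) {
  pmin(pmax(round((t_ms - signal$t0) / 1000 * signal$sampling_rate) + 1L, 1L),
       length(signal$samples))
}

# threshold-crossing scan: last index at/before `from` (direction -1) or
# first at/after (direction +1) where y stays below thr for two samples
scan_crossing <- function(y, from, limit, thr, direction) {
  i <- from
  while (i != limit) {
    j <- i + direction
    if (y[i] < thr && y[j] < thr) return(i)
    i <- j
  }
  limit
}

# refine a threshold crossing towards the true wave boundary by
# extrapolating the local tangent to baseline; with a noise-adapted
# threshold the crossing sits well inside the wave, and the tangent
# removes most of that bias
tangent_boundary <- function(y, cross_idx, dt, direction, h = 2L,
                             max_corr_ms = 6) {
  n <- length(y)
  a <- max(1L, cross_idx - h)
  b <- min(n, cross_idx + h)
  slope <- (y[b] - y[a]) / ((b - a) * dt)       # mV per ms
  v <- y[cross_idx]
  # rising edge when scanning left (direction -1), falling when right
  usable <- (direction < 0 && slope > 0) || (direction > 0 && slope < 0)
  if (!usable || v <= 0) return(0)
  min(v / abs(slope), max_corr_ms)               # outward shift magnitude
}

#' Delineate beats around detected R peaks
#'
#' For each R peak, locates QRS onset/offset by threshold crossing of the
#' smoothed signal, searches a PR window (default 12-80 ms before QRS
#' onset) for a P wave, and measures T end by the tangent method on the
#' descending T limb (murine T merges with the terminal QRS, so T end is
#' the tangent-baseline intersection). Beats without a P deflection above
#' threshold are classed ventricular; P-like deflections with no QRS
#' within the association window become non-conducted atrial events.
#' Fusion labels are copied from `truth` when supplied — automatic fusion
#' calling from morphology is out of scope.
#'
#' @param signal An [ecg_signal()].
#' @param r_peaks R-peak times in ms, from [detect_r_peaks()].
#' @param truth Optional [synth_truth()] used only to transfer fusion-beat
#'   labels.
#' @param pr_search P search window before QRS onset, ms (min, max).
#' @param p_assoc_ms Maximum P-to-QRS distance for association, ms.
#' @return A `beat_fiducials` tibble, one row per beat or atrial event,
#'   with columns `class` (`sinus`/`ventricular`/`fusion`/`atrial`),
#'   `conducted`, `p_onset`, `p_offset`, `qrs_onset`, `r_peak`,
#'   `qrs_offset`, `t_end`, `pr` (ms; absent fiducials are `NA`).
#'   Per-beat failures yield `NA` fiducials, never an error.
#' @export
delineate_beats <- function(signal, r_peaks, truth = NULL,
                            pr_search = c(12, 80), p_assoc_ms = 100) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$sampling_rate
  x <- signal$samples
  nx <- length(x)
  dt <- 1000 / fs
  base <- median(x)
  w_fine <- max(3L, round(0.0015 * fs))
  w_coarse <- max(5L, round(0.004 * fs))
  xs <- moving_average(x, w_fine) - base
  xp <- moving_average(x, w_coarse) - base
  noise_sd <- mad(x - moving_average(x, 5L)) + 1e-12
  t_of <- function(i) signal$t0 + (i - 1) * dt

  r_peaks <- sort(r_peaks)
  nb <- length(r_peaks)
  if (!nb) {
    out <- tibble::tibble(class = character(), conducted = logical(),
                          p_onset = numeric(), p_offset = numeric(),
                          qrs_onset = numeric(), r_peak = numeric(),
                          qrs_offset = numeric(), t_end = numeric(),
                          pr = numeric())
    class(out) <- c("beat_fiducials", class(out))
    return(out)
  }
  r_idx <- idx_at(signal, r_peaks)
  r_amp_med <- median(xs[r_idx])
  p_thr <- max(0.06 * r_amp_med, 3.5 * noise_sd / sqrt(w_coarse))

  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    ri <- r_idx[b]
    A <- xs[ri]
    thr_q <- max(0.02 * A, 2.5 * noise_sd / sqrt(w_fine))
    lim_l <- max(1L, ri - round(0.030 * fs))
    lim_r <- min(nx, ri + round(0.030 * fs))
    on_i <- scan_crossing(xs, ri, lim_l, thr_q, -1L)
    off_i <- scan_crossing(xs, ri, lim_r, thr_q, +1L)
    qrs_on <- t_of(on_i) - tangent_boundary(xs, on_i, dt, -1L, max_corr_ms = 2)
    qrs_off <- t_of(off_i) + tangent_boundary(xs, off_i, dt, +1L, max_corr_ms = 2)

    # P search window before QRS onset
    w_lo <- max(1L, on_i - round(pr_search[2] / dt))
    w_hi <- max(1L, on_i - round(pr_search[1] / dt))
    p_on <- p_off <- NA_real_
    has_p <- FALSE
    if (w_hi > w_lo + 2L) {
      seg <- xp[w_lo:w_hi]
      # P must be an interior bump in the window; the decaying tail of the
      # previous T wave can exceed the threshold at the window edge but has
      # no interior local maximum there
      locmax <- which(diff(sign(diff(seg))) < 0) + 1L
      locmax <- locmax[seg[locmax] >= p_thr]
      pk <- if (length(locmax)) locmax[length(locmax)] else which.max(seg)
      if (length(locmax) && seg[pk] >= p_thr) {
        has_p <- TRUE
        pki <- w_lo + pk - 1L
        p_lvl <- max(0.05 * seg[pk], 2.5 * noise_sd / sqrt(w_coarse))
        p_on_i <- scan_crossing(xp, pki, max(1L, w_lo - round(0.015 * fs)),
                                p_lvl, -1L)
        p_off_i <- scan_crossing(xp, pki, min(nx, w_hi + round(0.008 * fs)),
                                 p_lvl, +1L)
        p_on <- t_of(p_on_i) - tangent_boundary(xp, p_on_i, dt, -1L)
        p_off <- min(t_of(p_off_i) + tangent_boundary(xp, p_off_i, dt, +1L),
                     qrs_on)
      }
    }

    # T end by tangent on the descending limb
    t_end <- NA_real_
    t_lo <- off_i + round(0.001 * fs)
    t_hi <- min(nx, off_i + round(0.060 * fs))
    if (b < nb) {
      next_on_est <- r_idx[b + 1] - round((pr_search[2] + 10) / dt)
      t_hi <- min(t_hi, next_on_est)
    }
    if (t_hi > t_lo + 4L) {
      seg <- xp[t_lo:t_hi]
      pk <- which.max(seg)
      if (seg[pk] >= max(0.02 * r_amp_med, 3 * noise_sd / sqrt(w_coarse))) {
        pki <- t_lo + pk - 1L
        tpk <- xp[pki]
        # tangent method: straight line fitted to the central descending
        # limb (25-80% of the T peak), extrapolated to baseline
        limb <- (pki + 1L):t_hi
        below <- which(xp[limb] < 0.1 * tpk)
        if (length(below)) limb <- limb[seq_len(below[1])]
        sel <- limb[xp[limb] <= 0.8 * tpk & xp[limb] >= 0.25 * tpk]
        if (length(sel) >= 4) {
          ft <- stats::lm.fit(cbind(1, t_of(sel)), xp[sel])
          sl <- ft$coefficients[2]
          if (is.finite(sl) && sl < 0) {
            t_end <- min(-ft$coefficients[1] / sl, t_of(t_hi) + 5)
          }
        }
      }
    }

    rows[[b]] <- data.frame(
      class = if (has_p) "sinus" else "ventricular",
      conducted = if (has_p) TRUE else NA,
      p_onset = p_on, p_offset = p_off,
      qrs_onset = qrs_on, r_peak = r_peaks[b], qrs_offset = qrs_off,
      t_end = t_end,
      pr = if (has_p) qrs_on - p_on else NA_real_
    )
  }
  fid <- do.call(rbind, rows)

  # orphan (non-conducted) P waves: deflections outside every beat's span
  mask <- rep(FALSE, nx)
  for (b in seq_len(nb)) {
    a <- fid$p_onset[b]
    if (is.na(a)) a <- fid$qrs_onset[b] - pr_search[1]
    # mask the full plausible T extent: the tangent t_end systematically
    # precedes the true end of the T lobe
    z <- max(fid$t_end[b], fid$qrs_offset[b] + 45, na.rm = TRUE)
    mask[seq(max(1L, idx_at(signal, a - 3)), min(nx, idx_at(signal, z + 3)))] <- TRUE
  }
  edge <- round(0.005 * fs)
  mask[seq_len(min(edge, nx))] <- TRUE
  mask[seq(max(1L, nx - edge), nx)] <- TRUE
  cand <- xp > p_thr & !mask
  runs <- true_runs(cand)
  if (nrow(runs)) {
    runs <- runs[runs$end - runs$start >= max(2L, round(0.003 * fs)), ,
                 drop = FALSE]
  }
  orphans <- NULL
  if (nrow(runs)) {
    orphans <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
      a <- runs$start[k]; b2 <- runs$end[k]
      pki <- a - 1L + which.max(xp[a:b2])
      p_lvl <- max(0.05 * xp[pki], 2 * noise_sd / sqrt(w_coarse))
      p_on_i <- scan_crossing(xp, pki, max(1L, a - round(0.015 * fs)), p_lvl, -1L)
      p_off_i <- scan_crossing(xp, pki, min(nx, b2 + round(0.015 * fs)), p_lvl, +1L)
      data.frame(class = "atrial", conducted = FALSE,
                 p_onset = t_of(p_on_i) - tangent_boundary(xp, p_on_i, dt, -1L),
                 p_offset = t_of(p_off_i) + tangent_boundary(xp, p_off_i, dt, +1L),
                 qrs_onset = NA_real_, r_peak = NA_real_,
                 qrs_offset = NA_real_, t_end = NA_real_, pr = NA_real_)
    }))
  }
  fid <- rbind(fid, orphans)
  ref <- ifelse(is.na(fid$r_peak), fid$p_onset, fid$r_peak)
  fid <- fid[order(ref), ]
  rownames(fid) <- NULL

  if (!is.null(truth)) {
    fus <- truth$events$r_peak[truth$events$class == "fusion"]
    if (length(fus)) {
      for (ft in fus) {
        d <- abs(fid$r_peak - ft)
        j <- which.min(ifelse(is.na(d), Inf, d))
        if (length(j) && !is.na(fid$r_peak[j]) && abs(fid$r_peak[j] - ft) < 10) {
          fid$class[j] <- "fusion"
        }
      }
    }
  }
  out <- tibble::as_tibble(fid)
  class(out) <- c("beat_fiducials", class(out))
  out
}

#' Average surface-ECG intervals over a window
#'
#' Means are taken over conducted sinus beats inside the half-open window
#' `[start, end)`; ventricular and fusion beats are excluded, and RR is
#' measured only between sinus beats that are consecutive in the record
#' (no intervening event of any kind). Heart rate is `60000 / mean(RR)`.
#'
#' @param fiducials A `beat_fiducials` table.
#' @param window `c(start_ms, end_ms)` or `NULL` for the whole record.
#' @param qtc_rr0 Normalization RR for the Mitchell correction, ms.
#' @return One-row tibble: `heart_rate` (bpm), `mean_rr`, `pr`,
#'   `p_duration`, `qrs`, `qt`, `qtc` (ms), `n_beats`, `window_start`,
#'   `window_end`.
#' @export
measure_intervals <- function(fiducials, window = NULL, qtc_rr0 = 100) {
  fid <- fiducials
  if (is.null(window)) {
    tt <- c(fid$r_peak, fid$p_onset)
    window <- c(min(tt, na.rm = TRUE), max(tt, na.rm = TRUE) + 1)
  }
  inside <- !is.na(fid$r_peak) & fid$r_peak >= window[1] & fid$r_peak < window[2]
  sinus <- inside & fid$class == "sinus" &
    (is.na(fid$conducted) | fid$conducted)
  if (sum(sinus) < 10) {
    stop_insufficient_data("interval averaging needs at least 10 conducted sinus beats in the window")
  }
  si <- which(sinus)
  adj <- si[-length(si)] + 1L == si[-1]          # consecutive rows in record
  rr <- (fid$r_peak[si[-1]] - fid$r_peak[si[-length(si)]])[adj]
  if (!length(rr)) {
    stop_insufficient_data("no consecutive sinus beat pairs for RR measurement")
  }
  mean_rr <- mean(rr)
  qt <- mean(fid$t_end[si] - fid$qrs_onset[si], na.rm = TRUE)
  tibble::tibble(
    heart_rate = 60000 / mean_rr,
    mean_rr = mean_rr,
    pr = mean(fid$pr[si], na.rm = TRUE),
    p_duration = mean(fid$p_offset[si] - fid$p_onset[si], na.rm = TRUE),
    qrs = mean(fid$qrs_offset[si] - fid$qrs_onset[si], na.rm = TRUE),
    qt = qt,
    qtc = correct_qt(qt, mean_rr, rr0 = qtc_rr0),
    n_beats = sum(sinus),
    window_start = window[1],
    window_end = window[2]
  )
}

#' Rate-corrected QT interval (Mitchell murine formula)
#'
#' `QTc = QT / sqrt(RR / 100)` with RR in ms — the murine convention
#' normalizes to an RR of 100 ms rather than the 1 s of the human Bazett
#' formula.
#'
#' @param qt QT interval in ms (> 0).
#' @param mean_rr Mean RR interval in ms (> 0).
#' @param rr0 Normalization RR, ms (default 100).
#' @return QTc in ms.
#' @export
correct_qt <- function(qt, mean_rr, rr0 = 100) {
  if (any(qt <= 0, na.rm = TRUE) || any(mean_rr <= 0, na.rm = TRUE)) {
    stop("`qt` and `mean_rr` must be positive")
  }
  qt / sqrt(mean_rr / rr0)
}
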