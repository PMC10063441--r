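#' Time-domain heart rate variability statistics
#'
#' Computes the standard murine time-domain panel over the included
#' intervals of a tachogram: mean and median RR, SDRR (sample SD of the RR
#' intervals), SDSD (sample SD of successive differences), RMSSD (root mean
#' square of successive differences) and pRR50 (percentage of successive
#' differences whose absolute value is strictly greater than `threshold_ms`).
#' Successive differences use only pairs of adjacent included intervals.
#'
#' @param rr An [rr_series()].
#' @param threshold_ms pRR threshold in ms (strict inequality), default 50.
#' @return A one-row tibble with columns `average_rr`, `median_rr`, `sdrr`,
#'   `sdsd`, `rmssd` (ms) and `prr50` (percent).
#' @export
hrv_time_domain <- function(rr, threshold_ms = 50) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr[rr$included]
  if (length(x) < 2) {
    stop_insufficient_data("time-domain HRV needs at least 2 included intervals")
  }
  d <- successive_diffs(rr)
  tibble::tibble(
    average_rr = mean(x),
    median_rr = median(x),
    sdrr = sd(x),
    sdsd = if (length(d) >= 2) sd(d) else NA_real_,
    rmssd = if (length(d) >= 1) sqrt(mean(d^2)) else NA_real_,
    prr50 = if (length(d) >= 1) 100 * mean(abs(d) > threshold_ms) else NA_real_
  )
}

#' Lomb normalized periodogram of the tachogram
#'
#' Evaluates the classical Lomb normalized periodogram of the unevenly
#' sampled tachogram (`rr[i]` against the beat time opening interval `i`),
#' after mean subtraction, on a uniform frequency grid. The periodogram is
#' normalized by twice the sample variance, so a pure sinusoidal modulation
#' of the intervals produces a peak of height about N/4 at its frequency.
#'
#' @param rr An [rr_series()]; at least 30 included intervals.
#' @param frequencies Frequency grid in Hz; defaults to 0.005 Hz steps over
#'   (0, 5] Hz, matching the murine band table.
#' @return An object of class `hrv_spectrum`: list with `frequencies`,
#'   `power`, `normalization` and a `degenerate` flag (constant series).
#' @export
lomb_periodogram <- function(rr, frequencies = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(frequencies)) frequencies <- seq(0.005, 5, by = 0.005)
  frequencies <- as.numeric(frequencies)
  if (any(diff(frequencies) <= 0) || any(frequencies <= 0)) {
    stop("`frequencies` must be positive and strictly increasing")
  }
  n_rr <- length(rr$rr)
  idx <- which(rr$included)
  if (length(idx) < 30) {
    stop_insufficient_data("Lomb periodogram needs at least 30 included intervals")
  }
  tt <- rr$beat_times[idx] / 1000          # seconds; interval opening times
  y <- rr$rr[idx]
  y <- y - mean(y)
  n <- length(y)
  s2 <- sum(y^2) / (n - 1)
  if (s2 <= .Machine$double.eps) {
    return(structure(
      list(frequencies = frequencies, power = rep(0, length(frequencies)),
           normalization = "lomb_normalized", degenerate = TRUE),
      class = "hrv_spectrum"
    ))
  }
  power <- vapply(frequencies, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * tt)), sum(cos(2 * w * tt))) / (2 * w)
    ct <- cos(w * (tt - tau))
    st <- sin(w * (tt - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  structure(
    list(frequencies = frequencies, power = power,
         normalization = "lomb_normalized", degenerate = FALSE),
    class = "hrv_spectrum"
  )
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("<hrv_spectrum> %d frequencies in [%.3f, %.3f] Hz%s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Spectral band percentages for murine HRV
#'
#' Integrates the periodogram by the trapezoidal rule and assigns each
#' trapezoidal panel to the band containing its midpoint, with murine band
#' edges VLF 0-0.15 Hz, LF 0.15-1.5 Hz, HF 1.5-5 Hz (half-open on the
#' right). Percentages are normalized to the VLF+LF+HF total, so they sum
#' to 100 by construction; LF/HF is the ratio of the percentages.
#'
#' @param spectrum An `hrv_spectrum` from [lomb_periodogram()].
#' @param edges Band edges in Hz: `c(vlf_lo, vlf_hi, lf_hi, hf_hi)`.
#' @return One-row tibble: `vlf_pct`, `lf_pct`, `hf_pct`, `lf_hf`.
#' @export
hrv_band_powers <- function(spectrum, edges = c(0, 0.15, 1.5, 5)) {
  stopifnot(inherits(spectrum, "hrv_spectrum"))
  if (isTRUE(spectrum$degenerate)) {
    stop_not_evaluable("degenerate (constant) spectrum: band percentages undefined")
  }
  f <- spectrum$frequencies
  p <- spectrum$power
  mid <- (f[-1] + f[-length(f)]) / 2
  area <- diff(f) * (p[-1] + p[-length(p)]) / 2
  vlf <- sum(area[mid >= edges[1] & mid < edges[2]])
  lf <- sum(area[mid >= edges[2] & mid < edges[3]])
  hf <- sum(area[mid >= edges[3] & mid < edges[4]])
  total <- vlf + lf + hf
  if (total <= 0) {
    stop_not_evaluable("no spectral power inside the band table")
  }
  tibble::tibble(
    vlf_pct = 100 * vlf / total,
    lf_pct = 100 * lf / total,
    hf_pct = 100 * hf / total,
    lf_hf = (100 * lf / total) / (100 * hf / total)
  )
}

#' Poincare plane dispersion (SD1/SD2)
#'
#' Plots each included RR interval against its successor and measures the
#' dispersion of the cloud perpendicular to (`sd1`) and along (`sd2`) the
#' identity line: `sd1 = SD((rr_n - rr_{n+1}) / sqrt(2))`,
#' `sd2 = SD((rr_n + rr_{n+1}) / sqrt(2))`. The default population (1/n)
#' variance convention makes the algebraic identities
#' `sd1 = sdsd_pop / sqrt(2)` and `sd1^2 + sd2^2 = 2 sdrr_pop^2` exact on
#' the paired subseries.
#'
#' @param rr An [rr_series()]; at least 3 included intervals.
#' @param convention `"population"` (default) or `"sample"` SD.
#' @return One-row tibble with `sd1` and `sd2` in ms.
#' @export
poincare <- function(rr, convention = c("population", "sample")) {
  stopifnot(inherits(rr, "rr_series"))
  convention <- match.arg(convention)
  pairs <- adjacent_pairs(rr)
  if (nrow(pairs) < 2 || sum(rr$included) < 3) {
    stop_insufficient_data("Poincare analysis needs at least 3 included intervals")
  }
  sdfun <- if (convention == "population") pop_sd else sd
  tibble::tibble(
    sd1 = sdfun((pairs[, 1] - pairs[, 2]) / sqrt(2)),
    sd2 = sdfun((pairs[, 1] + pairs[, 2]) / sqrt(2))
  )
}

#' All Fig.-style HRV quantities for one tachogram
#'
#' Convenience wrapper producing the full HRV panel (time domain, band
#' percentages from the Lomb periodogram, Poincare SD1/SD2) as a single row.
#'
#' @inheritParams hrv_time_domain
#' @param frequencies Optional frequency grid passed to [lomb_periodogram()].
#' @return One-row tibble.
#' @export
hrv_panel <- function(rr, threshold_ms = 50, frequencies = NULL) {
  td <- hrv_time_domain(rr, threshold_ms = threshold_ms)
  fd <- hrv_band_powers(lomb_periodogram(rr, frequencies = frequencies))
  pc <- poincare(rr)
  tibble::as_tibble(cbind(td, fd, pc))
}
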