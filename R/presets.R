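#' Autonomic-tone presets for the RR generator
#'
#' An autonomic preset parameterises the interval-domain model behind
#' [generate_rr_series()]: a mean RR interval modulated by a low-frequency
#' (baroreflex-range) sinusoid, a high-frequency (respiratory/vagal)
#' sinusoid, a very slow wander term and additive white noise. The three
#' named presets are calibrated so that the full analysis pipeline
#' reproduces the group structure observed in awake mice and under
#' medetomidine/midazolam/fentanyl (MMF) or isoflurane/fentanyl (IF)
#' narcosis: awake median RR near 126 ms with balanced spectral content,
#' MMF near 227 ms with dominant high-frequency vagal modulation (RMSSD on
#' the order of 130 ms, pRR50 well above the other groups), IF near 157 ms
#' and awake-like variability.
#'
#' @param name One of `"awake"`, `"mmf"`, `"if"`, or `"custom"`.
#' @param mean_rr Mean RR interval in ms.
#' @param lf_amp,lf_freq Low-frequency modulation: amplitude as a fraction
#'   of `mean_rr`, frequency in Hz (must lie in the murine LF band,
#'   0.15-1.5 Hz).
#' @param hf_amp,hf_freq High-frequency modulation: fraction of `mean_rr`
#'   and Hz (murine HF band, 1.5-5 Hz).
#' @param wander_amp,wander_freq Very-low-frequency drift: fraction of
#'   `mean_rr` and Hz (must lie in the VLF band, below 0.15 Hz).
#' @param noise_sd Additive white noise on each interval, ms.
#' @param seed Integer seed; generation is deterministic given the preset.
#' @return An object of class `autonomic_preset`.
#' @export
autonomic_preset <- function(name = c("awake", "mmf", "if", "custom"),
                             mean_rr = NULL,
                             lf_amp = NULL, lf_freq = NULL,
                             hf_amp = NULL, hf_freq = NULL,
                             wander_amp = NULL, wander_freq = NULL,
                             noise_sd = NULL, seed = 1L) {
  name <- match.arg(name)
  base <- switch(name,
    awake = list(mean_rr = 126.1, lf_amp = 0.045, lf_freq = 0.40,
                 hf_amp = 0.050, hf_freq = 2.5, wander_amp = 0.060,
                 wander_freq = 0.05, noise_sd = 3.0),
    mmf   = list(mean_rr = 227.3, lf_amp = 0.040, lf_freq = 0.40,
                 hf_amp = 0.410, hf_freq = 2.5, wander_amp = 0.010,
                 wander_freq = 0.05, noise_sd = 5.0),
    `if`  = list(mean_rr = 157.5, lf_amp = 0.040, lf_freq = 0.40,
                 hf_amp = 0.045, hf_freq = 2.5, wander_amp = 0.050,
                 wander_freq = 0.05, noise_sd = 2.5),
    custom = list(mean_rr = 150, lf_amp = 0, lf_freq = 0.4,
                  hf_amp = 0, hf_freq = 2.5, wander_amp = 0,
                  wander_freq = 0.05, noise_sd = 0)
  )
  override <- list(mean_rr = mean_rr, lf_amp = lf_amp, lf_freq = lf_freq,
                   hf_amp = hf_amp, hf_freq = hf_freq,
                   wander_amp = wander_amp, wander_freq = wander_freq,
                   noise_sd = noise_sd)
  for (f in names(override)) {
    if (!is.null(override[[f]])) base[[f]] <- override[[f]]
  }
  preset <- c(list(name = name), base, list(seed = as.integer(seed)))
  class(preset) <- "autonomic_preset"
  validate_preset(preset)
  preset
}

validate_preset <- function(p) {
  if (!is.numeric(p$mean_rr) || p$mean_rr <= 0) {
    stop("`mean_rr` must be positive")
  }
  amps <- c(p$lf_amp, p$hf_amp, p$wander_amp)
  if (any(amps < 0)) stop("modulation amplitudes must be non-negative")
  if (sum(amps) >= 1) {
    stop("lf_amp + hf_amp + wander_amp must be < 1 so intervals stay positive")
  }
  if (p$lf_amp > 0 && (p$lf_freq <= 0.15 || p$lf_freq > 1.5)) {
    stop("`lf_freq` must lie in the LF band (0.15, 1.5] Hz")
  }
  if (p$hf_amp > 0 && (p$hf_freq <= 1.5 || p$hf_freq > 5.0)) {
    stop("`hf_freq` must lie in the HF band (1.5, 5.0] Hz")
  }
  if (p$wander_amp > 0 && (p$wander_freq <= 0 || p$wander_freq >= 0.15)) {
    stop("`wander_freq` must lie in the VLF band (0, 0.15) Hz")
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be non-negative")
  invisible(p)
}

#' @export
print.autonomic_preset <- function(x, ...) {
  cat(sprintf(
    paste0("<autonomic_preset '%s'> mean RR %.1f ms; LF %.3f @ %.2f Hz; ",
           "HF %.3f @ %.2f Hz; wander %.3f @ %.3f Hz; noise %.1f ms; seed %d\n"),
    x$name, x$mean_rr, x$lf_amp, x$lf_freq, x$hf_amp, x$hf_freq,
    x$wander_amp, x$wander_freq, x$noise_sd, x$seed
  ))
  invisible(x)
}
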