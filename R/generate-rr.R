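#' Generate a synthetic RR tachogram from an autonomic preset
#'
#' Point-process construction: starting at time 0, each interval is
#' evaluated at the current cumulative beat time `t` as
#' `RR = mean_rr * (1 + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi hf_freq t)
#'  + wander_amp sin(2 pi wander_freq t)) + N(0, noise_sd)`,
#' and the next beat is placed `RR` ms later. The resulting series is the
#' unevenly sampled tachogram the Lomb periodogram expects.
#'
#' @param preset An [autonomic_preset()].
#' @param duration_s Record length in seconds (at least 10).
#' @return An [rr_series()] whose last beat time is the first to reach
#'   `duration_s`.
#' @export
generate_rr_series <- function(preset, duration_s) {
  stopifnot(inherits(preset, "autonomic_preset"))
  validate_preset(preset)
  if (duration_s < 10) stop("`duration_s` must be at least 10 s")
  end_ms <- duration_s * 1000
  with_seed(preset$seed, {
    # generous preallocation: shortest credible interval
    cap <- ceiling(end_ms / (preset$mean_rr * (1 - preset$lf_amp -
                                                 preset$hf_amp -
                                                 preset$wander_amp))) + 16L
    times <- numeric(cap)
    t <- 0
    n <- 1L
    while (t < end_ms) {
      ts <- t / 1000
      mod <- 1 +
        preset$lf_amp * sin(2 * pi * preset$lf_freq * ts) +
        preset$hf_amp * sin(2 * pi * preset$hf_freq * ts) +
        preset$wander_amp * sin(2 * pi * preset$wander_freq * ts)
      rr <- preset$mean_rr * mod + rnorm(1L, 0, preset$noise_sd)
      if (rr <= 0) {
        stop("non-positive RR interval generated; preset amplitudes/noise too large")
      }
      t <- t + rr
      n <- n + 1L
      if (n > length(times)) times <- c(times, numeric(cap))
      times[n] <- t
    }
    rr_series(times[seq_len(n)])
  })
}
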