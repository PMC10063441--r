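#' Beat-to-beat RR interval series
#'
#' The tachogram container used by all HRV computations. Intervals are
#' defined as `rr[i] = beat_times[i + 1] - beat_times[i]` (ms); `included`
#' is a per-interval mask used to exclude intervals adjacent to ectopy or
#' artifact from time-domain and Poincare statistics.
#'
#' @param beat_times Strictly increasing beat times in ms from record start.
#' @param included Logical mask, one entry per interval. Defaults to all
#'   `TRUE`.
#' @return An object of class `rr_series` with elements `beat_times`, `rr`
#'   and `included`.
#' @export
rr_series <- function(beat_times, included = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    stop("`beat_times` must contain at least two beats")
  }
  rr <- diff(beat_times)
  if (any(rr <= 0)) {
    stop("`beat_times` must be strictly increasing")
  }
  if (is.null(included)) included <- rep(TRUE, length(rr))
  if (length(included) != length(rr)) {
    stop("`included` must have one entry per interval")
  }
  structure(
    list(beat_times = beat_times, rr = rr, included = as.logical(included)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals over %.1f s (mean RR %.1f ms, %d excluded)\n",
    length(x$rr), diff(range(x$beat_times)) / 1000,
    mean(x$rr), sum(!x$included)
  ))
  invisible(x)
}

#' @export
as.data.frame.rr_series <- function(x, ...) {
  data.frame(
    beat_time_ms = x$beat_times[-length(x$beat_times)],
    rr_ms = x$rr,
    included = x$included
  )
}

# consecutive-pair successive differences restricted to the included mask:
# a difference rr[i+1] - rr[i] is usable only when both intervals are included
successive_diffs <- function(rr) {
  n <- length(rr$rr)
  if (n < 2) return(numeric(0))
  keep <- rr$included[-n] & rr$included[-1]
  diff(rr$rr)[keep]
}

# adjacent included (rr_n, rr_{n+1}) pairs for the Poincare plane
adjacent_pairs <- function(rr) {
  n <- length(rr$rr)
  if (n < 2) return(cbind(numeric(0), numeric(0)))
  keep <- rr$included[-n] & rr$included[-1]
  cbind(rr$rr[-n][keep], rr$rr[-1][keep])
}
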