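# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state seeded by `seed`; the caller's
# global RNG state is untouched, which is what makes whole-study runs
# bit-reproducible regardless of surrounding code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_insufficient_data <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("murineEP_insufficient_data", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_not_evaluable <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("murineEP_not_evaluable", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# centered moving average with edge padding (width in samples)
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  cs <- c(0, cumsum(xp))
  half <- w %/% 2L
  i <- seq_len(n) + w          # index into xp of each original sample
  (cs[i + (w - half)] - cs[i - half]) / w
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# maximal runs of TRUE in a logical vector -> list of start/end indices
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
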