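rr_from <- function(x) rr_series(cumsum(c(0, x)))

test_that("time-domain statistics match hand-computed values", {
  td <- hrv_time_domain(rr_from(c(100, 100, 100, 100)))
  expect_equal(td$sdrr, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$prr50, 0)

  td <- hrv_time_domain(rr_from(c(120, 180, 120, 180, 120)))
  expect_equal(td$rmssd, 60)
  expect_equal(td$prr50, 100)
  expect_equal(td$sdrr, sd(c(120, 180, 120, 180, 120)))
  expect_equal(round(td$sdrr, 2), 32.86)

  # strict inequality: differences of exactly 50 ms do not count
  td <- hrv_time_domain(rr_from(c(100, 150, 100, 150, 100)))
  expect_equal(td$prr50, 0)

  expect_error(hrv_time_domain(rr_from(150)), class = "murineEP_insufficient_data")
})

test_that("Poincare, SDSD and RMSSD identities hold on random series", {
  set.seed(11)
  for (k in 1:100) {
    x <- 150 + rnorm(sample(20:80, 1), 0, sample(c(2, 10, 25), 1))
    x <- pmax(x, 5)
    rr <- rr_from(x)
    pc <- poincare(rr)
    d <- diff(x)
    expect_equal(pc$sd1, pop_sd_oracle(d) / sqrt(2), tolerance = 1e-9)
    expect_equal(pc$sd1^2 + pc$sd2^2,
                 pop_sd_oracle(x[-length(x)])^2 + pop_sd_oracle(x[-1])^2,
                 tolerance = 1e-9)
    td <- hrv_time_domain(rr)
    expect_equal(td$rmssd^2, pop_sd_oracle(d)^2 + mean(d)^2,
                 tolerance = 1e-9)
  }
})

test_that("alternating series approaches the Poincare limit", {
  rr <- rr_from(rep(c(120, 180), 100))
  pc <- poincare(rr)
  expect_equal(pc$sd1, 60 / sqrt(2), tolerance = 0.01)
  expect_lt(pc$sd2, 1)
  pc0 <- poincare(rr_from(rep(150, 20)))
  expect_equal(pc0$sd1, 0)
  expect_equal(pc0$sd2, 0)
})

test_that("HRV statistics scale with the series; pRR50 stays absolute", {
  set.seed(4)
  x <- 150 + rnorm(100, 0, 20)
  a <- cbind(hrv_time_domain(rr_from(x)), poincare(rr_from(x)))
  b <- cbind(hrv_time_domain(rr_from(2.5 * x)), poincare(rr_from(2.5 * x)))
  for (col in c("average_rr", "median_rr", "sdrr", "sdsd", "rmssd",
                "sd1", "sd2")) {
    expect_equal(b[[col]], 2.5 * a[[col]], tolerance = 1e-9, label = col)
  }
  # the 50 ms threshold is absolute, so scaling changes the percentage
  expect_gt(b$prr50, a$prr50)
})

test_that("Lomb periodogram matches the least-squares oracle", {
  rr <- generate_rr_series(autonomic_preset("awake", seed = 3), 45)
  expect_lte(length(rr$rr), 500)
  set.seed(5)
  freqs <- sort(sample(seq(0.01, 5, by = 0.01), 80))
  mine <- lomb_periodogram(rr, frequencies = freqs)$power
  oracle <- lomb_lm_oracle(rr, freqs)
  denom <- pmax(oracle, 1e-6 * max(oracle))
  expect_lt(max(abs(mine - oracle) / denom), 1e-8)
})

test_that("single-tone modulation peaks at the injected frequency", {
  for (f0 in c(0.5, 3.0)) {
    p <- autonomic_preset("custom", mean_rr = 150,
                          lf_amp = if (f0 < 1.5) 0.15 else 0,
                          lf_freq = max(f0, 0.2),
                          hf_amp = if (f0 >= 1.5) 0.15 else 0,
                          hf_freq = max(f0, 2))
    rr <- generate_rr_series(p, 120)
    sp <- lomb_periodogram(rr)
    pk <- sp$frequencies[which.max(sp$power)]
    expect_lte(abs(pk - f0), 0.005 + 1e-9)
  }
})

test_that("degenerate spectra are flagged and rejected downstream", {
  rr <- rr_from(rep(150, 40))
  sp <- lomb_periodogram(rr)
  expect_true(sp$degenerate)
  expect_true(all(sp$power == 0))
  expect_error(hrv_band_powers(sp), class = "murineEP_not_evaluable")
  expect_error(lomb_periodogram(rr_from(rep(150, 10))),
               class = "murineEP_insufficient_data")
})

test_that("band percentages isolate single tones and sum to 100", {
  hf_rr <- generate_rr_series(
    autonomic_preset("custom", mean_rr = 150, hf_amp = 0.15, hf_freq = 3),
    120)
  bp <- hrv_band_powers(lomb_periodogram(hf_rr))
  expect_gte(bp$hf_pct, 95)
  lf_rr <- generate_rr_series(
    autonomic_preset("custom", mean_rr = 150, lf_amp = 0.15, lf_freq = 0.5),
    120)
  bl <- hrv_band_powers(lomb_periodogram(lf_rr))
  expect_gte(bl$lf_pct, 95)
  expect_gt(bl$lf_hf, 10)
  for (b in list(bp, bl)) {
    expect_equal(b$vlf_pct + b$lf_pct + b$hf_pct, 100, tolerance = 1e-9)
    expect_equal(b$lf_hf, b$lf_pct / b$hf_pct, tolerance = 1e-12)
  }
})

test_that("equal-amplitude tones in both bands balance LF/HF", {
  # mean RR 110 ms keeps the beat rate high enough (9 Hz) that the
  # spectral mirror of the 3 Hz tone falls above the 5 Hz band table;
  # at slower rates the mirror lands inside the HF band and the band
  # integral double-counts the HF tone
  rr <- generate_rr_series(
    autonomic_preset("custom", mean_rr = 110, lf_amp = 0.10, lf_freq = 0.5,
                     hf_amp = 0.10, hf_freq = 3),
    240)
  sp <- lomb_periodogram(rr)
  b <- hrv_band_powers(sp)
  expect_gt(b$lf_hf, 0.9)
  expect_lt(b$lf_hf, 1.1)
  # two distinct peaks with comparable power
  near <- function(f0) max(sp$power[abs(sp$frequencies - f0) <= 0.02])
  expect_lt(abs(near(0.5) - near(3)) / max(near(0.5), near(3)), 0.10)
})

test_that("the excluded-interval mask removes intervals from statistics", {
  x <- c(rep(150, 20), 400, rep(150, 20))   # one artifact interval
  inc <- rep(TRUE, length(x)); inc[21] <- FALSE
  masked <- hrv_time_domain(rr_series(cumsum(c(0, x)), included = inc))
  expect_equal(masked$sdrr, 0)
  expect_equal(masked$rmssd, 0)
  raw <- hrv_time_domain(rr_from(x))
  expect_gt(raw$sdrr, 10)
})
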