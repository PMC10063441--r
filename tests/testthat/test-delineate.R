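awake_truth <- function(seed = 3, duration = 30) {
  rr <- generate_rr_series(autonomic_preset("awake", seed = seed), duration)
  synth_truth(rr, pr = 38.05, p_dur = 11.65, qrs_dur = 10, qt = 39.3)
}

test_that("R detection is exact on clean input and degrades gracefully", {
  truth <- awake_truth()
  sim <- synthesize_ecg(truth)
  rp <- detect_r_peaks(sim$signal)
  tr <- truth$events$r_peak
  expect_equal(length(rp), length(tr))
  dt <- 1000 / sim$signal$sampling_rate
  expect_lte(max(abs(sort(rp) - sort(tr))), dt + 1e-9)
  # lockout: no two detections closer than 20 ms
  expect_true(all(diff(sort(rp)) >= 20))

  flat <- ecg_signal(rep(0, 4000), 2000)
  expect_warning(out <- detect_r_peaks(flat), "flatline")
  expect_length(out, 0)
  expect_error(detect_r_peaks(ecg_signal(rnorm(100), 2000)), "1 s")
})

test_that("R detection keeps sensitivity and PPV above 99% at SNR 10", {
  truth <- awake_truth(seed = 21, duration = 60)
  sim <- synthesize_ecg(truth, noise_sd = 0.1, seed = 8)  # R amplitude 1 mV
  rp <- detect_r_peaks(sim$signal)
  tr <- truth$events$r_peak
  sens <- mean(vapply(tr, function(t) min(abs(rp - t)) < 5, logical(1)))
  ppv <- mean(vapply(rp, function(t) min(abs(tr - t)) < 5, logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(ppv, 0.99)
})

test_that("delineated intervals recover truth within tolerance", {
  truth <- awake_truth()
  sim <- synthesize_ecg(truth)
  fid <- delineate_beats(sim$signal, detect_r_peaks(sim$signal))
  expect_true(all(fid$class == "sinus"))
  iv <- measure_intervals(fid)
  expect_lt(abs(iv$pr - 38.05), 2)
  expect_lt(abs(iv$p_duration - 11.65), 2)
  expect_lt(abs(iv$qrs - 10), 2)
  expect_lt(abs(iv$qt - 39.3), 5)       # tangent T end, widened tolerance
  # HR/RR reciprocity is exact as computed
  expect_equal(iv$heart_rate * iv$mean_rr, 60000, tolerance = 1e-12)

  # per-beat PR against truth
  tf <- truth_fiducials(truth)
  idx <- vapply(tf$r_peak, function(t) which.min(abs(fid$r_peak - t)),
                integer(1))
  expect_lt(max(abs(fid$pr[idx] - tf$pr)), 2)
})

test_that("interval means stay within 5 ms of truth at SNR 10", {
  truth <- awake_truth(seed = 5)
  sim <- synthesize_ecg(truth, noise_sd = 0.1, seed = 13)
  fid <- delineate_beats(sim$signal, detect_r_peaks(sim$signal))
  iv <- measure_intervals(fid)
  expect_lt(abs(iv$pr - 38.05), 5)
  expect_lt(abs(iv$p_duration - 11.65), 5)
  expect_lt(abs(iv$qrs - 10), 5)
  expect_lt(abs(iv$qt - 39.3), 5)
})

test_that("beat classes follow the P-wave evidence", {
  truth <- regular_truth(n = 30, rr = 150)
  truth <- inject_conduction_disorder(truth, "ventricular_run", start = 10,
                                      run_length = 4)
  truth <- inject_conduction_disorder(truth, "intermittent_avb3",
                                      start = 20, run_length = 2)
  sim <- synthesize_ecg(truth)
  fid <- delineate_beats(sim$signal, detect_r_peaks(sim$signal))
  expect_equal(sum(fid$class == "ventricular"), 4)
  expect_true(all(is.na(fid$p_onset[fid$class == "ventricular"])))
  atr <- fid[fid$class == "atrial", ]
  expect_equal(nrow(atr), 2)
  expect_true(all(!atr$conducted))
  dropped <- truth$events[truth$events$class == "sinus" &
                            !truth$events$conducted, ]
  expect_lt(max(abs(sort(atr$p_onset) - sort(dropped$p_onset))), 3)
})

test_that("interval averaging demands ten usable sinus beats", {
  truth <- regular_truth(n = 30, rr = 150)
  vr <- inject_conduction_disorder(truth, "ventricular_run", start = 2,
                                   run_length = 28)
  expect_error(measure_intervals(truth_fiducials(vr)),
               class = "murineEP_insufficient_data")
  expect_error(measure_intervals(truth_fiducials(regular_truth(n = 5))),
               class = "murineEP_insufficient_data")
})

test_that("windowed interval means follow the window's beats", {
  # alternating RR 100/200: heart rate = 60000 / 150 = 400 bpm
  beats <- cumsum(c(100, rep(c(100, 200), 10)))
  truth <- synth_truth(beats, pr = 38, p_dur = 11, qrs_dur = 10, qt = 30,
                       beats_as = "r_peak")
  iv <- measure_intervals(truth_fiducials(truth))
  expect_equal(iv$heart_rate, 400)
  # uniform truth at the awake working point
  beats2 <- seq(100, by = 123.5, length.out = 30)
  truth2 <- synth_truth(beats2, pr = 38, p_dur = 11.65, qrs_dur = 10,
                        qt = 30, beats_as = "r_peak")
  iv2 <- measure_intervals(truth_fiducials(truth2))
  expect_equal(iv2$heart_rate, 60000 / 123.5, tolerance = 1e-9)
  expect_equal(iv2$pr, 38)
  expect_equal(iv2$p_duration, 11.65)
})

test_that("disjoint windows of a stationary record agree", {
  truth <- awake_truth(seed = 17, duration = 60)
  sim <- synthesize_ecg(truth)
  fid <- delineate_beats(sim$signal, detect_r_peaks(sim$signal))
  a <- measure_intervals(fid, window = c(0, 30000))
  b <- measure_intervals(fid, window = c(30000, 60000))
  for (col in c("pr", "p_duration", "qrs", "qt")) {
    expect_lt(abs(a[[col]] - b[[col]]), 1, label = col)
  }
})

test_that("the Mitchell correction normalizes QT to RR 100 ms", {
  expect_equal(correct_qt(50, 100), 50)
  expect_equal(correct_qt(50, 400), 25)
  expect_equal(correct_qt(30, 225), 20)
  expect_error(correct_qt(-1, 100), "positive")
})
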