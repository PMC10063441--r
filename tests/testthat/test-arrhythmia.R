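test_that("a regular record produces no sinus-arrhythmia episodes", {
  fid <- truth_fiducials(regular_truth(n = 60, rr = 150))
  expect_equal(nrow(detect_sinus_arrhythmia(fid)), 0)
  expect_error(detect_sinus_arrhythmia(truth_fiducials(regular_truth(n = 20))),
               class = "murineEP_insufficient_data")
})

test_that("injected sinus arrhythmia is recovered with >= 90% overlap", {
  rr <- generate_rr_series(autonomic_preset("mmf", hf_amp = 0.12, seed = 5), 40)
  truth <- synth_truth(rr, pr = 54, p_dur = 18.7, qrs_dur = 10, qt = 52)
  truth <- inject_conduction_disorder(truth, "sinus_arrhythmia", start = 20,
                                      n_beats = 40)
  inj <- injected_episodes(truth)
  eps <- detect_sinus_arrhythmia(truth_fiducials(truth))
  expect_gte(nrow(eps), 1)
  cover <- sum(vapply(seq_len(nrow(eps)), function(i) {
    max(0, min(eps$offset[i], inj$offset) - max(eps$onset[i], inj$onset))
  }, numeric(1)))
  expect_gte(cover / (inj$offset - inj$onset), 0.9)
})

test_that("irregularity caused solely by AV-block pauses is not sinus arrhythmia", {
  truth <- regular_truth(n = 80, rr = 150)
  truth <- inject_conduction_disorder(truth, "intermittent_avb3", start = 20,
                                      run_length = 2, n_runs = 4,
                                      gap_beats = 8)
  fid <- truth_fiducials(truth)
  sa <- detect_sinus_arrhythmia(fid)
  expect_equal(nrow(sa), 0)
  expect_gt(nrow(detect_av_block(fid)), 0)
})

test_that("Wenckebach pattern detection follows the PR-prolongation rule", {
  truth <- regular_truth(n = 30, rr = 150)
  truth <- inject_conduction_disorder(truth, "wenckebach", start = 10, k = 3,
                                      n_cycles = 1, pr_start = 35,
                                      pr_increment = 10)
  eps <- detect_av_block(truth_fiducials(truth))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$kind, "avb2_wenckebach")
  expect_equal(eps$n_beats, 4)          # three prolonging beats + dropped P

  # constant PR, fully conducted: nothing to report
  expect_equal(nrow(detect_av_block(truth_fiducials(regular_truth(40)))), 0)
  # records without any P annotation are not evaluable (distinct from "no block")
  vr <- inject_conduction_disorder(regular_truth(40), "ventricular_run",
                                   start = 1, run_length = 40)
  expect_error(detect_av_block(truth_fiducials(vr)),
               class = "murineEP_not_evaluable")
})

test_that("runs of dropped P waves classify as intermittent third-degree block", {
  truth <- regular_truth(n = 30, rr = 150)
  truth <- inject_conduction_disorder(truth, "intermittent_avb3", start = 10,
                                      run_length = 3)
  eps <- detect_av_block(truth_fiducials(truth))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$kind, "avb3")
  expect_equal(eps$n_beats, 3)
})

test_that("Wenckebach and third-degree episodes never share a dropped P", {
  truth <- regular_truth(n = 60, rr = 150)
  truth <- inject_conduction_disorder(truth, "wenckebach", start = 8, k = 2,
                                      n_cycles = 2, pr_start = 35,
                                      pr_increment = 8)
  truth <- inject_conduction_disorder(truth, "intermittent_avb3", start = 30,
                                      run_length = 2, n_runs = 2,
                                      gap_beats = 6)
  eps <- detect_av_block(truth_fiducials(truth))
  expect_equal(sum(eps$kind == "avb2_wenckebach"), 2)
  expect_equal(sum(eps$kind == "avb3"), 2)
  # episode spans of the two kinds are disjoint
  w <- eps[eps$kind == "avb2_wenckebach", ]
  t3 <- eps[eps$kind == "avb3", ]
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(nrow(t3))) {
      expect_true(w$offset[i] <= t3$onset[j] || t3$offset[j] <= w$onset[i])
    }
  }
})

test_that("ventricular activity needs at least four consecutive beats", {
  base <- regular_truth(n = 40, rr = 150)
  four <- inject_conduction_disorder(base, "ventricular_run", start = 10,
                                     run_length = 4)
  eps <- detect_ventricular_activity(truth_fiducials(four))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_beats, 4)

  # three consecutive ventricular beats do not qualify: build directly
  fid3 <- truth_fiducials(four)
  vi3 <- which(fid3$class == "ventricular")
  fid3$class[vi3[4]] <- "sinus"
  expect_equal(nrow(detect_ventricular_activity(fid3)), 0)

  two_runs <- inject_conduction_disorder(four, "ventricular_run", start = 25,
                                         run_length = 5)
  eps2 <- detect_ventricular_activity(truth_fiducials(two_runs))
  expect_equal(nrow(eps2), 2)
  expect_equal(sort(eps2$n_beats), c(4L, 5L))
})

test_that("fusion beats are transparent to ventricular runs", {
  truth <- regular_truth(n = 20, rr = 150)
  truth <- inject_conduction_disorder(truth, "ventricular_run", start = 5,
                                      run_length = 4)
  fid <- truth_fiducials(truth)
  vi <- which(fid$class == "ventricular")
  fid$class[vi[2]] <- "fusion"          # interrupts the run morphologically
  eps <- detect_ventricular_activity(fid)
  expect_equal(nrow(eps), 0)            # only 3 ventricular beats remain
  fid$class[vi[2]] <- "ventricular"
  fid$class[vi[1] - 1] <- "fusion"      # fusion at the boundary
  expect_equal(nrow(detect_ventricular_activity(fid)), 1)
})

test_that("detections are invariant to prepended and appended sinus rhythm", {
  truth <- regular_truth(n = 60, rr = 150)
  truth <- inject_conduction_disorder(truth, "wenckebach", start = 25, k = 3,
                                      n_cycles = 1, pr_start = 35,
                                      pr_increment = 10)
  truth <- inject_conduction_disorder(truth, "ventricular_run", start = 40,
                                      run_length = 4)
  fid <- truth_fiducials(truth)
  n <- nrow(fid)
  middle <- fid[10:n, ]                 # drop quiet lead-in
  e_full <- rbind(detect_av_block(fid), detect_ventricular_activity(fid))
  e_mid <- rbind(detect_av_block(middle), detect_ventricular_activity(middle))
  expect_equal(e_full[c("kind", "onset", "offset", "n_beats")],
               e_mid[c("kind", "onset", "offset", "n_beats")])
})

test_that("episode recovery is exact (Jaccard 1 at 50 ms) on truth annotations", {
  truth <- regular_truth(n = 80, rr = 150)
  truth <- inject_conduction_disorder(truth, "wenckebach", start = 10, k = 3,
                                      n_cycles = 2, pr_start = 35,
                                      pr_increment = 10)
  truth <- inject_conduction_disorder(truth, "intermittent_avb3", start = 30,
                                      run_length = 2, n_runs = 2,
                                      gap_beats = 8)
  truth <- inject_conduction_disorder(truth, "ventricular_run", start = 55,
                                      run_length = 5)
  fid <- truth_fiducials(truth)
  det <- rbind(detect_av_block(fid), detect_ventricular_activity(fid))
  inj <- injected_episodes(truth)
  inj$kind[inj$kind == "wenckebach"] <- "avb2_wenckebach"
  inj$kind[inj$kind == "intermittent_avb3"] <- "avb3"
  inj$kind[inj$kind == "ventricular_run"] <- "ventricular_activity"
  expect_equal(nrow(det), nrow(inj))
  det <- det[order(det$onset), ]
  inj <- inj[order(inj$onset), ]
  expect_equal(det$kind, inj$kind)
  expect_lte(max(abs(det$onset - inj$onset)), 50)
  expect_lte(max(abs(det$offset - inj$offset)), 50)
})

test_that("prevalence summaries report fractions of flagged animals", {
  mk <- function(subject, group, flagged) {
    truth <- regular_truth(n = 60, rr = 150)
    if (flagged) {
      truth <- inject_conduction_disorder(truth, "ventricular_run",
                                          start = 20, run_length = 4)
    }
    rhythm_findings(truth_fiducials(truth), subject, group)
  }
  findings <- c(
    lapply(1:9, function(i) mk(paste0("m", i), "mmf", TRUE)),
    list(mk("m10", "mmf", FALSE)),
    lapply(1:12, function(i) mk(paste0("i", i), "if", FALSE))
  )
  prev <- summarize_prevalence(findings)
  va <- prev[prev$kind == "ventricular_activity", ]
  expect_equal(va$pct[va$group == "mmf"], 90)
  expect_equal(va$pct[va$group == "if"], 0)
  expect_equal(va$n_animals[va$group == "if"], 12)
})
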