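test_that("corrected SNRT is the return pause minus the basic cycle length", {
  evs <- rbind(
    event_row((0:9) * 150, "sense", "atrium", "sinus", 0, "baseline"),
    event_row(2000 + (0:249) * 120, "stimulus", "atrium", "S1", 1, "snrt",
              drive_cl = 120),
    event_row(2000 + 249 * 120 + 250, "sense", "atrium", "sinus_return", 1,
              "snrt", drive_cl = 120)
  )
  log <- make_stim_log(evs, protocol_row(1, "snrt", "atrium", drive_cl = 120))
  expect_equal(measure_basic_cl(log), 150)
  v <- compute_snrt(log, 120)
  expect_true(is.na(v$censored))
  expect_equal(v$value, 100)

  # return exactly at the basic cycle length gives zero corrected SNRT
  evs2 <- evs[evs$label != "sinus_return", ]
  evs2 <- rbind(evs2, event_row(2000 + 249 * 120 + 150, "sense", "atrium",
                                "sinus_return", 1, "snrt", drive_cl = 120))
  log2 <- make_stim_log(evs2, protocol_row(1, "snrt", "atrium", drive_cl = 120))
  expect_equal(compute_snrt(log2, 120)$value, 0)

  # no return within 5 s: sinus arrest, censored
  log3 <- make_stim_log(evs[evs$label != "sinus_return", ],
                        protocol_row(1, "snrt", "atrium", drive_cl = 120))
  v3 <- compute_snrt(log3, 120)
  expect_true(is.na(v3$value))
  expect_equal(v3$note, "sinus_arrest")
})

test_that("conduction endpoints follow their definitions on constructed ramps", {
  # {90: 1:1, 85: 1:1, 80: Wenckebach} -> WB CL 80
  log <- ramp_log(c(90, 85, 80), c(20, 20, 15))
  expect_equal(find_conduction_cl(log, "wenckebach")$value, 80)
  # 1:1 at every tested CL: censored below the ramp
  all11 <- ramp_log(c(90, 85, 80), c(20, 20, 20))
  expect_equal(find_conduction_cl(all11, "wenckebach")$censored, "below_range")
  # failure already at the longest tested CL: censored above
  allwb <- ramp_log(c(90, 85, 80), c(15, 15, 10))
  expect_equal(find_conduction_cl(allwb, "wenckebach")$censored, "above_range")
  # 2:1 pattern
  log21 <- ramp_log(c(90, 80, 70, 60), c(20, 15, 10, 10))
  expect_equal(find_conduction_cl(log21, "two_to_one")$value, 70)
  # retrograde: longest ventricular CL with VA block
  va <- ramp_log(c(80, 90, 100, 110), c(0, 0, 20, 20), type = "va_ramp",
                 stim_chamber = "ventricle", resp_chamber = "atrium")
  expect_equal(find_conduction_cl(va, "retrograde")$value, 90)
})

test_that("ERP is the longest failing coupling, with censoring and warnings", {
  log <- erp_scan_log(c(60, 55, 50, 45), c(TRUE, TRUE, FALSE, FALSE))
  v <- compute_erp(log, "ventricle", 120)
  expect_equal(v$value, 50)

  none <- erp_scan_log(c(60, 55, 50), c(TRUE, TRUE, TRUE))
  expect_equal(compute_erp(none, "ventricle", 120)$censored, "below_range")
  all_fail <- erp_scan_log(c(60, 55, 50), c(FALSE, FALSE, FALSE))
  expect_equal(compute_erp(all_fail, "ventricle", 120)$censored, "above_range")

  blip <- erp_scan_log(c(60, 55, 50, 45), c(TRUE, FALSE, TRUE, FALSE))
  expect_warning(vb <- compute_erp(blip, "ventricle", 120), "non-monotonic")
  expect_equal(vb$value, 55)
})

test_that("the simulator round-trips EP parameters to within one step", {
  h <- virtual_heart_params(basic_cl = 120, snrt_true = 208, aerp_true = 39,
                            verp_true = 46, averp_true = 71, wb_cl_true = 89,
                            two_to_one_cl_true = 70, va_cl_true = 118,
                            atrial_induction_prob = 0,
                            ventricular_induction_prob = 0, seed = 2)
  prot <- ep_protocol()
  prot <- prot[prot$type %in% c("snrt", "avn_ramp", "va_ramp", "erp"), ]
  log <- simulate_ep_responses(h, prot)
  pars <- analyze_ep(log)
  val <- function(p, d = NA) {
    r <- pars[pars$parameter == p &
                (is.na(d) | (!is.na(pars$drive_cl) & pars$drive_cl == d)), ]
    r$value[1]
  }
  expect_equal(val("snrt_corrected", 120), 208 - 120, tolerance = 1e-9)
  expect_lte(89 - val("wb_cl"), 5); expect_gte(89, val("wb_cl"))
  expect_lte(70 - val("two_to_one_cl"), 5)
  expect_lte(118 - val("va_cl"), 5)
  expect_lte(39 - val("aerp", 120), 5)
  expect_lte(71 - val("averp", 100), 5)
  expect_lte(46 - val("verp", 120), 5)

  # a 2 ms S1/S2 scan narrows VERP recovery to 2 ms
  prot2 <- ep_protocol(erp_couplings = seq(80, 15, by = -2))
  prot2 <- prot2[prot2$type == "erp" & prot2$tissue == "ventricle" &
                   prot2$drive_cl == 120, ]
  log2 <- simulate_ep_responses(h, prot2)
  v2 <- compute_erp(log2, "ventricle", 120)
  expect_lte(46 - v2$value, 2)
  expect_gte(46, v2$value)
})

test_that("episode qualification respects the 3 s and 4 beat boundaries", {
  mk_atrial <- function(dur_s) {
    evs <- rbind(
      event_row((0:7) * 120, "stimulus", "atrium", "S1", 1, "induction",
                drive_cl = 120),
      event_row(7 * 120 + 40, "stimulus", "atrium", "S2", 1, "induction",
                drive_cl = 120, coupling = 40),
      event_row(1000 + seq(0, dur_s * 1000, by = 50), "sense", "atrium",
                "atrial_ectopic", 1, "induction")
    )
    make_stim_log(evs, protocol_row(1, "induction", "atrium",
                                    drive_cl = 120, coupling = 40))
  }
  expect_equal(nrow(detect_induced_episodes(mk_atrial(3.0), "atrium")), 1)
  expect_equal(nrow(detect_induced_episodes(mk_atrial(2.9), "atrium")), 0)

  mk_vent <- function(n_beats) {
    evs <- rbind(
      event_row((0:7) * 120, "stimulus", "ventricle", "S1", 1, "induction",
                drive_cl = 120),
      event_row(1000 + (seq_len(n_beats) - 1) * 100, "sense", "ventricle",
                "ventricular_ectopic", 1, "induction")
    )
    make_stim_log(evs, protocol_row(1, "induction", "ventricle",
                                    drive_cl = 120, coupling = 40))
  }
  expect_equal(nrow(detect_induced_episodes(mk_vent(4), "ventricle")), 1)
  expect_equal(nrow(detect_induced_episodes(mk_vent(3), "ventricle")), 0)
})

test_that("inducibility and burden aggregate as stated", {
  h0 <- virtual_heart_params(atrial_induction_prob = 0,
                             ventricular_induction_prob = 0, seed = 3)
  prot <- ep_protocol()
  prot <- prot[prot$type %in% c("induction", "burst"), ]
  log <- simulate_ep_responses(h0, prot)
  ia <- inducibility_and_burden(detect_induced_episodes(log, "atrium"),
                                log, "atrium")
  expect_equal(ia$inducibility_pct, 0)
  expect_equal(ia$burden_s, 0)

  # arithmetic: 2 successes over 44 maneuvers
  expect_equal(100 * 2 / 44, 4.545455, tolerance = 1e-6)

  # cohort totals are exact sums of animal burdens
  per <- tibble::tibble(
    subject_id = c("a", "b", "c"), chamber = "atrium",
    n_success = c(2L, 0L, 1L), n_maneuvers = c(24L, 24L, 24L),
    inducibility_pct = 100 * c(2, 0, 1) / 24,
    mean_episode_s = c(10, 0, 4), burden_s = c(20, 0, 4)
  )
  co <- cohort_inducibility(per)
  expect_equal(co$total_burden_s, 24)
  expect_equal(co$burden_per_animal_s, 8)
  expect_equal(co$burden_per_inducible_animal_s, 12)
  expect_equal(co$inducibility_pct, 100 * 3 / 72)
})

test_that("simulated inducibility matches the programmed probability", {
  prot <- ep_protocol()
  prot <- prot[prot$type %in% c("induction", "burst") &
                 prot$chamber == "atrium", ]
  succ <- 0L; total <- 0L
  for (s in 1:42) {
    h <- virtual_heart_params(atrial_induction_prob = 0.05,
                              ventricular_induction_prob = 0, seed = 100 + s)
    log <- simulate_ep_responses(h, prot)
    ia <- inducibility_and_burden(detect_induced_episodes(log, "atrium"),
                                  log, "atrium")
    succ <- succ + ia$n_success
    total <- total + ia$n_maneuvers
  }
  expect_gte(total, 1000)
  ci <- qbinom(c(0.025, 0.975), total, 0.05) / total
  expect_gte(succ / total, ci[1])
  expect_lte(succ / total, ci[2])
})

test_that("protocols cannot address chambers the catheter cannot reach", {
  expect_error(ep_protocol(chambers = c("atrium", "esophagus")),
               "cannot stimulate")
})
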