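#' Virtual-heart parameters with ground-truth EP properties
#'
#' Conduction behaviour of the virtual heart is threshold-deterministic:
#' a premature stimulus captures iff its coupling interval exceeds the
#' tissue's true refractory period, atrial pacing conducts 1:1 iff the
#' cycle length exceeds the true Wenckebach cycle length (with a
#' Wenckebach drop pattern between the Wenckebach and 2:1 thresholds, 2:1
#' conduction at or below the 2:1 threshold), and ventricular pacing
#' conducts retrogradely iff the cycle length exceeds the true VA
#' conduction cycle length. Only arrhythmia induction and episode duration
#' are stochastic, which makes refractory-period and cycle-length recovery
#' exact while preserving inducibility statistics.
#'
#' @param basic_cl Intrinsic sinus cycle length, ms.
#' @param snrt_true Pause from last overdrive stimulus to the first sinus
#'   return beat (uncorrected), ms.
#' @param aerp_true,verp_true,averp_true True atrial / ventricular / AV
#'   nodal effective refractory periods, ms. The AV nodal value need not
#'   exceed the atrial one (independent tissues).
#' @param wb_cl_true,two_to_one_cl_true,va_cl_true True Wenckebach, 2:1
#'   and retrograde conduction cycle lengths, ms;
#'   `two_to_one_cl_true < wb_cl_true` is required.
#' @param atrial_induction_prob,ventricular_induction_prob Probability
#'   that one stimulation maneuver induces a qualifying episode.
#' @param atrial_episode_s,ventricular_episode_s `c(mean, sd)` of episode
#'   durations in seconds; atrial draws are truncated at the 3 s
#'   qualification bound, ventricular episodes always contain at least 4
#'   beats.
#' @param seed Integer seed; simulation is deterministic given the params.
#' @return Object of class `virtual_heart_params`.
#' @export
virtual_heart_params <- function(basic_cl = 240, snrt_true = 330,
                                 aerp_true = 39, verp_true = 46,
                                 averp_true = 71,
                                 wb_cl_true = 89, two_to_one_cl_true = 70,
                                 va_cl_true = 118,
                                 atrial_induction_prob = 0.03,
                                 ventricular_induction_prob = 0.01,
                                 atrial_episode_s = c(26, 15),
                                 ventricular_episode_s = c(1.2, 0.4),
                                 seed = 1L) {
  p <- list(basic_cl = basic_cl, snrt_true = snrt_true,
            aerp_true = aerp_true, verp_true = verp_true,
            averp_true = averp_true, wb_cl_true = wb_cl_true,
            two_to_one_cl_true = two_to_one_cl_true, va_cl_true = va_cl_true,
            atrial_induction_prob = atrial_induction_prob,
            ventricular_induction_prob = ventricular_induction_prob,
            atrial_episode_s = atrial_episode_s,
            ventricular_episode_s = ventricular_episode_s,
            seed = as.integer(seed))
  ms <- c("basic_cl", "snrt_true", "aerp_true", "verp_true", "averp_true",
          "wb_cl_true", "two_to_one_cl_true", "va_cl_true")
  for (f in ms) if (p[[f]] <= 0) stop(sprintf("`%s` must be positive", f))
  if (p$two_to_one_cl_true >= p$wb_cl_true) {
    stop("`two_to_one_cl_true` must be smaller than `wb_cl_true`")
  }
  for (f in c("atrial_induction_prob", "ventricular_induction_prob")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(sprintf("`%s` must be in [0, 1]", f))
  }
  class(p) <- "virtual_heart_params"
  p
}

#' Group-level virtual hearts for the two narcosis regimens
#'
#' Draws one animal's virtual heart around the group means observed under
#' MMF or IF narcosis (bradycardic, sinus- and AV-node-depressed MMF
#' versus near-physiological IF), with per-animal Gaussian jitter scaled
#' to the group dispersions. Invariants (positive values, 2:1 CL below
#' WB CL) are enforced after jittering.
#'
#' @param group `"mmf"` or `"if"`.
#' @param seed Per-animal seed.
#' @return A [virtual_heart_params()].
#' @export
virtual_heart_preset <- function(group = c("mmf", "if"), seed = 1L) {
  group <- match.arg(group)
  base <- switch(group,
    mmf = list(basic_cl = c(242, 12), snrt_off = c(88, 40), wb = c(89, 15),
               two21 = c(70, 7), va = c(118, 12), averp = c(71, 12),
               aerp = c(39, 7), verp = c(46, 6),
               a_prob = 0.0318, v_prob = 0.0126,
               a_ep = c(26.5, 15), v_ep = c(1.2, 0.4)),
    `if` = list(basic_cl = c(158, 10), snrt_off = c(25, 12), wb = c(80, 5),
                two21 = c(55, 5), va = c(91, 9), averp = c(54, 8),
                aerp = c(41, 5), verp = c(45, 6),
                a_prob = 0.0472, v_prob = 0,
                a_ep = c(9.5, 6), v_ep = c(1.2, 0.4))
  )
  with_seed(seed, {
    g <- function(ms) max(ms[1] + rnorm(1, 0, ms[2]), 0.2 * ms[1])
    basic <- g(base$basic_cl)
    wb <- g(base$wb)
    two21 <- min(g(base$two21), wb - 5)
    virtual_heart_params(
      basic_cl = basic,
      snrt_true = basic + max(g(base$snrt_off), 5),
      aerp_true = g(base$aerp), verp_true = g(base$verp),
      averp_true = g(base$averp),
      wb_cl_true = wb, two_to_one_cl_true = max(two21, 20),
      va_cl_true = g(base$va),
      atrial_induction_prob = base$a_prob,
      ventricular_induction_prob = base$v_prob,
      atrial_episode_s = base$a_ep, ventricular_episode_s = base$v_ep,
      seed = seed
    )
  })
}

#' Standard programmed-stimulation protocol
#'
#' The maneuver roster of a murine transjugular EP study: 30 s overdrive
#' drives at 120 and 100 ms for sinus node recovery, a decremental atrial
#' ramp for Wenckebach and 2:1 cycle lengths, an incremental (fast to
#' slow) ventricular ramp for retrograde conduction, S1/S2 refractory
#' scans of atrium, ventricle and AV node at both drive cycle lengths,
#' S1/S2/S3 double-extrastimulus induction at coupling intervals 40-20 ms
#' in 5 ms decrements, and 3 s and 6 s bursts at cycle lengths 40-10 ms in
#' 5 ms decrements, in both chambers.
#'
#' @param drive_cls Drive-train cycle lengths, ms.
#' @param ramp_cls Atrial decremental ramp for AV conduction, ms.
#' @param va_cls Ventricular ramp (ascending cycle lengths), ms.
#' @param erp_couplings S1/S2 coupling scan, ms (descending).
#' @param induction_couplings S2/S3 couplings for induction, ms.
#' @param burst_cls,burst_durations_s Burst cycle lengths (ms) and
#'   durations (s).
#' @param chambers Chambers stimulated for induction.
#' @return Tibble of maneuvers (class `ep_protocol`), in execution order.
#' @export
ep_protocol <- function(drive_cls = c(120, 100),
                        ramp_cls = seq(130, 40, by = -5),
                        va_cls = seq(50, 160, by = 5),
                        erp_couplings = seq(80, 15, by = -5),
                        induction_couplings = seq(40, 20, by = -5),
                        burst_cls = seq(40, 10, by = -5),
                        burst_durations_s = c(3, 6),
                        chambers = c("atrium", "ventricle")) {
  bad <- setdiff(chambers, c("atrium", "ventricle"))
  if (length(bad)) {
    stop(sprintf("catheter cannot stimulate chamber: %s",
                 paste(bad, collapse = ", ")))
  }
  man <- list()
  add <- function(type, chamber, drive_cl = NA, cl = NA, coupling = NA,
                  tissue = NA, burst_s = NA) {
    man[[length(man) + 1L]] <<- data.frame(
      type = type, chamber = chamber, drive_cl = drive_cl, cl = cl,
      coupling = coupling, tissue = tissue, burst_s = burst_s
    )
  }
  for (d in drive_cls) add("snrt", "atrium", drive_cl = d)
  for (cl in ramp_cls) add("avn_ramp", "atrium", cl = cl)
  for (cl in va_cls) add("va_ramp", "ventricle", cl = cl)
  for (tissue in c("atrium", "ventricle", "av_node")) {
    ch <- if (tissue == "ventricle") "ventricle" else "atrium"
    for (d in drive_cls) {
      for (cp in erp_couplings) {
        add("erp", ch, drive_cl = d, coupling = cp, tissue = tissue)
      }
    }
  }
  for (ch in chambers) {
    for (d in drive_cls) {
      for (cp in induction_couplings) {
        add("induction", ch, drive_cl = d, coupling = cp)
      }
    }
    for (bs in burst_durations_s) {
      for (cl in burst_cls) {
        add("burst", ch, cl = cl, burst_s = bs)
      }
    }
  }
  out <- do.call(rbind, man)
  out$maneuver_id <- seq_len(nrow(out))
  out <- tibble::as_tibble(out)
  class(out) <- c("ep_protocol", class(out))
  out
}

stim_event <- function(time, kind, chamber, label, maneuver_id,
                       maneuver_type, drive_cl = NA, coupling = NA) {
  data.frame(time = time, kind = kind, chamber = chamber, label = label,
             maneuver_id = maneuver_id, maneuver_type = maneuver_type,
             drive_cl = drive_cl, coupling = coupling)
}

#' Simulate an EP study on a virtual heart
#'
#' Executes the protocol against the threshold-deterministic virtual
#' heart and returns the resulting stimulus/response event log. Capture
#' and conduction outcomes follow the thresholds in
#' [virtual_heart_params()]; the first sinus return after overdrive
#' arrives exactly `snrt_true` ms after the last drive stimulus;
#' induction maneuvers succeed as Bernoulli draws and, when successful,
#' append a qualifying episode of sampled duration (rapid ectopic atrial
#' activity, or a run of at least four ventricular beats). A block of
#' intrinsic sinus beats precedes the protocol so the basic cycle length
#' can be measured from the log itself.
#'
#' @param heart A [virtual_heart_params()].
#' @param protocol An [ep_protocol()].
#' @param gap_ms Quiet gap between maneuvers, ms.
#' @return Object of class `stim_log`: list with `events` (tibble) and the
#'   executed `protocol`.
#' @export
simulate_ep_responses <- function(heart, protocol = ep_protocol(),
                                  gap_ms = 2000) {
  stopifnot(inherits(heart, "virtual_heart_params"),
            inherits(protocol, "ep_protocol"))
  ev <- list()
  emit <- function(e) ev[[length(ev) + 1L]] <<- e
  t <- 0
  # intrinsic rhythm for basic cycle length measurement
  emit(stim_event(t + (0:10) * heart$basic_cl, "sense", "atrium", "sinus",
                  0L, "baseline"))
  t <- t + 10 * heart$basic_cl + gap_ms

  with_seed(heart$seed, {
    for (i in seq_len(nrow(protocol))) {
      m <- protocol[i, ]
      id <- m$maneuver_id
      if (m$type == "snrt") {
        n <- floor(30000 / m$drive_cl)
        st <- t + (seq_len(n) - 1) * m$drive_cl
        emit(stim_event(st, "stimulus", "atrium", "S1", id, "snrt",
                        drive_cl = m$drive_cl))
        ret <- st[n] + heart$snrt_true
        emit(stim_event(ret, "sense", "atrium", "sinus_return", id, "snrt",
                        drive_cl = m$drive_cl))
        t <- ret + gap_ms
      } else if (m$type == "avn_ramp") {
        n <- 20L
        st <- t + (seq_len(n) - 1) * m$cl
        emit(stim_event(st, "stimulus", "atrium", "S1", id, "avn_ramp"))
        cond <- if (m$cl > heart$wb_cl_true) {
          seq_len(n)
        } else if (m$cl > heart$two_to_one_cl_true) {
          which(seq_len(n) %% 4 != 0)          # Wenckebach-like 3:4 pattern
        } else {
          which(seq_len(n) %% 2 == 1)          # 2:1
        }
        if (length(cond)) {
          emit(stim_event(st[cond] + 25, "sense", "ventricle",
                          "conducted_response", id, "avn_ramp"))
        }
        t <- st[n] + gap_ms
      } else if (m$type == "va_ramp") {
        n <- 20L
        st <- t + (seq_len(n) - 1) * m$cl
        emit(stim_event(st, "stimulus", "ventricle", "S1", id, "va_ramp"))
        if (m$cl > heart$va_cl_true) {
          emit(stim_event(st + 30, "sense", "atrium", "conducted_response",
                          id, "va_ramp"))
        }
        t <- st[n] + gap_ms
      } else if (m$type == "erp") {
        st <- t + (0:7) * m$drive_cl
        s2 <- st[8] + m$coupling
        ch <- m$chamber
        emit(stim_event(st, "stimulus", ch, "S1", id, "erp",
                        drive_cl = m$drive_cl))
        emit(stim_event(s2, "stimulus", ch, "S2", id, "erp",
                        drive_cl = m$drive_cl, coupling = m$coupling))
        if (m$tissue == "atrium" && m$coupling > heart$aerp_true) {
          emit(stim_event(s2 + 2, "sense", "atrium", "capture", id, "erp",
                          drive_cl = m$drive_cl, coupling = m$coupling))
        } else if (m$tissue == "ventricle" && m$coupling > heart$verp_true) {
          emit(stim_event(s2 + 2, "sense", "ventricle", "capture", id, "erp",
                          drive_cl = m$drive_cl, coupling = m$coupling))
        } else if (m$tissue == "av_node" && m$coupling > heart$aerp_true) {
          emit(stim_event(s2 + 2, "sense", "atrium", "capture", id, "erp",
                          drive_cl = m$drive_cl, coupling = m$coupling))
          if (m$coupling > heart$averp_true) {
            emit(stim_event(s2 + 30, "sense", "ventricle",
                            "conducted_response", id, "erp",
                            drive_cl = m$drive_cl, coupling = m$coupling))
          }
        }
        t <- s2 + gap_ms
      } else if (m$type %in% c("induction", "burst")) {
        if (m$type == "induction") {
          st <- t + (0:7) * m$drive_cl
          s2 <- st[8] + m$coupling
          s3 <- s2 + m$coupling
          emit(stim_event(st, "stimulus", m$chamber, "S1", id, "induction",
                          drive_cl = m$drive_cl))
          emit(stim_event(c(s2, s3), "stimulus", m$chamber, c("S2", "S3"),
                          id, "induction", drive_cl = m$drive_cl,
                          coupling = m$coupling))
          t_end_stim <- s3
        } else {
          n <- max(2L, floor(m$burst_s * 1000 / m$cl))
          st <- t + (seq_len(n) - 1) * m$cl
          emit(stim_event(st, "stimulus", m$chamber, "burst", id, "burst"))
          t_end_stim <- st[n]
        }
        prob <- if (m$chamber == "atrium") heart$atrial_induction_prob
                else heart$ventricular_induction_prob
        success <- runif(1) < prob
        if (success) {
          if (m$chamber == "atrium") {
            d <- max(3, rnorm(1, heart$atrial_episode_s[1],
                              heart$atrial_episode_s[2]))
            et <- t_end_stim + 50 + seq(0, d * 1000, by = 50)
            emit(stim_event(et, "sense", "atrium", "atrial_ectopic", id,
                            m$type))
          } else {
            d <- max(0.4, rnorm(1, heart$ventricular_episode_s[1],
                                heart$ventricular_episode_s[2]))
            nb <- max(4L, round(d * 1000 / 100) + 1L)
            et <- t_end_stim + 80 + (seq_len(nb) - 1) * 100
            emit(stim_event(et, "sense", "ventricle", "ventricular_ectopic",
                            id, m$type))
          }
          t_end_stim <- max(et)
        }
        t <- t_end_stim + gap_ms
      }
    }
  })
  events <- tibble::as_tibble(do.call(rbind, ev))
  events <- events[order(events$time), ]
  structure(list(events = events, protocol = protocol), class = "stim_log")
}

#' @export
print.stim_log <- function(x, ...) {
  cat(sprintf("<stim_log> %d events, %d maneuvers (%.1f min)\n",
              nrow(x$events), nrow(x$protocol),
              diff(range(x$events$time)) / 60000))
  invisible(x)
}
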