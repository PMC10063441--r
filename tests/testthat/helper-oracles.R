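# Independent oracles and small fixture builders used across the suite.

# Least-squares evaluation of the Lomb periodogram: at each frequency the
# normalized Lomb power equals the chi-square reduction of fitting
# y ~ a cos(wt) + b sin(wt) to the mean-subtracted tachogram, divided by
# twice the sample variance. This route shares no code with the
# tau-rotation implementation under test.
lomb_lm_oracle <- function(rr, frequencies) {
  tt <- rr$beat_times[seq_along(rr$rr)][rr$included] / 1000
  y <- rr$rr[rr$included]
  y <- y - mean(y)
  n <- length(y)
  s2 <- sum(y^2) / (n - 1)
  rss0 <- sum(y^2)
  vapply(frequencies, function(f) {
    X <- cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    (rss0 - rss) / (2 * s2)
  }, numeric(1))
}

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# fraction of episode `b` covered by episode `a`
overlap_frac <- function(a_on, a_off, b_on, b_off) {
  inter <- max(0, min(a_off, b_off) - max(a_on, b_on))
  inter / (b_off - b_on)
}

# every truth episode matched by a detected episode of the same kind
# covering at least `min_frac` of its span, and vice versa
episodes_match <- function(detected, truth_eps, min_frac = 0.5) {
  cover <- function(from, to) {
    vapply(seq_len(nrow(to)), function(i) {
      same <- from[from$kind == to$kind[i], , drop = FALSE]
      if (!nrow(same)) return(FALSE)
      any(vapply(seq_len(nrow(same)), function(j) {
        overlap_frac(same$onset[j], same$offset[j],
                     to$onset[i], to$offset[i]) >= min_frac
      }, logical(1)))
    }, logical(1))
  }
  all(cover(detected, truth_eps)) && all(cover(truth_eps, detected))
}

# regular sinus truth at fixed RR (ms), n beats
regular_truth <- function(n = 40, rr = 150, pr = 38, p_dur = 11.65,
                          qrs = 10, qt = 36) {
  synth_truth(seq(0, by = rr, length.out = n) + 100, pr = pr, p_dur = p_dur,
              qrs_dur = qrs, qt = qt, beats_as = "atrial")
}

# hand-built stimulation log: events tibble + minimal protocol roster
make_stim_log <- function(events, protocol) {
  structure(list(events = tibble::as_tibble(events),
                 protocol = {
                   p <- tibble::as_tibble(protocol)
                   class(p) <- c("ep_protocol", class(p))
                   p
                 }),
            class = "stim_log")
}

event_row <- function(time, kind, chamber, label, maneuver_id,
                      maneuver_type, drive_cl = NA, coupling = NA) {
  data.frame(time = time, kind = kind, chamber = chamber, label = label,
             maneuver_id = maneuver_id, maneuver_type = maneuver_type,
             drive_cl = drive_cl, coupling = coupling)
}

protocol_row <- function(maneuver_id, type, chamber, drive_cl = NA, cl = NA,
                         coupling = NA, tissue = NA, burst_s = NA) {
  data.frame(type = type, chamber = chamber, drive_cl = drive_cl, cl = cl,
             coupling = coupling, tissue = tissue, burst_s = burst_s,
             maneuver_id = maneuver_id)
}

# constructed conduction-ramp log: one maneuver per CL with the given
# number of stimuli and conducted responses
ramp_log <- function(cls, conducted_of_20, type = "avn_ramp",
                     stim_chamber = "atrium", resp_chamber = "ventricle") {
  evs <- list(); t <- 0
  for (k in seq_along(cls)) {
    st <- t + (0:19) * cls[k]
    evs[[length(evs) + 1L]] <- event_row(st, "stimulus", stim_chamber, "S1",
                                         k, type)
    nc <- conducted_of_20[k]
    if (nc > 0) {
      idx <- round(seq(1, 20, length.out = nc))
      evs[[length(evs) + 1L]] <- event_row(st[idx] + 20, "sense",
                                           resp_chamber,
                                           "conducted_response", k, type)
    }
    t <- st[20] + 1000
  }
  prot <- do.call(rbind, lapply(seq_along(cls), function(k) {
    protocol_row(k, type, stim_chamber, cl = cls[k])
  }))
  make_stim_log(do.call(rbind, evs), prot)
}

# constructed S1/S2 scan log for one tissue/drive
erp_scan_log <- function(couplings, captured, tissue = "ventricle",
                         drive_cl = 120) {
  ch <- if (tissue == "ventricle") "ventricle" else "atrium"
  evs <- list(); t <- 0
  for (k in seq_along(couplings)) {
    st <- t + (0:7) * drive_cl
    s2 <- st[8] + couplings[k]
    evs[[length(evs) + 1L]] <- event_row(st, "stimulus", ch, "S1", k, "erp",
                                         drive_cl = drive_cl)
    evs[[length(evs) + 1L]] <- event_row(s2, "stimulus", ch, "S2", k, "erp",
                                         drive_cl = drive_cl,
                                         coupling = couplings[k])
    if (captured[k]) {
      evs[[length(evs) + 1L]] <- event_row(s2 + 2, "sense", ch, "capture",
                                           k, "erp", drive_cl = drive_cl,
                                           coupling = couplings[k])
    }
    t <- s2 + 1000
  }
  prot <- do.call(rbind, lapply(seq_along(couplings), function(k) {
    protocol_row(k, "erp", ch, drive_cl = drive_cl,
                 coupling = couplings[k], tissue = tissue)
  }))
  make_stim_log(do.call(rbind, evs), prot)
}
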