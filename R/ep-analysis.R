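# measured EP quantity with explicit censoring state
ep_value <- function(value, censored = NA_character_, note = NA_character_) {
  structure(list(value = value, censored = censored, note = note),
            class = "ep_value")
}

#' @export
print.ep_value <- function(x, ...) {
  if (is.na(x$censored)) {
    cat(sprintf("%.2f ms\n", x$value))
  } else {
    cat(sprintf("censored (%s)\n", x$censored))
  }
  invisible(x)
}

#' Basic atrial cycle length from the intrinsic rhythm block
#'
#' @param log A `stim_log`.
#' @return Mean sinus cycle length (ms) measured before the first stimulus.
#' @export
measure_basic_cl <- function(log) {
  stopifnot(inherits(log, "stim_log"))
  ev <- log$events
  first_stim <- suppressWarnings(min(ev$time[ev$kind == "stimulus"]))
  s <- ev$time[ev$kind == "sense" & ev$label == "sinus" & ev$time < first_stim]
  if (length(s) < 2) stop_not_evaluable("no intrinsic rhythm block in the log")
  mean(diff(sort(s)))
}

#' Corrected sinus node recovery time
#'
#' The pause from the last overdrive stimulus to the first sinus return
#' beat, minus the basic atrial cycle length. Missing sinus return within
#' 5 s is reported as sinus arrest (censored value).
#'
#' @param log A `stim_log`.
#' @param drive_cl Overdrive cycle length of the maneuver, ms.
#' @return An `ep_value` (ms; censored with note `"sinus_arrest"` when no
#'   return beat was sensed).
#' @export
compute_snrt <- function(log, drive_cl) {
  stopifnot(inherits(log, "stim_log"))
  ev <- log$events
  basic <- measure_basic_cl(log)
  stim <- ev[ev$kind == "stimulus" & ev$maneuver_type == "snrt" &
               !is.na(ev$drive_cl) & ev$drive_cl == drive_cl, ]
  if (!nrow(stim)) stop_not_evaluable("no overdrive maneuver at this drive CL")
  last <- max(stim$time)
  ret <- ev$time[ev$kind == "sense" & ev$label == "sinus_return" &
                   ev$time > last & ev$time <= last + 5000]
  if (!length(ret)) {
    return(ep_value(NA_real_, censored = "no_return", note = "sinus_arrest"))
  }
  ep_value((min(ret) - last) - basic)
}

#' Conduction cycle-length endpoints from pacing ramps
#'
#' * `wenckebach`: longest atrial pacing cycle length at which 1:1 AV
#'   conduction fails.
#' * `two_to_one`: longest cycle length showing 2:1 conduction.
#' * `retrograde`: longest ventricular pacing cycle length at which
#'   ventriculo-atrial conduction fails (a larger value means worse
#'   retrograde conduction).
#'
#' An endpoint whose true value lies outside the tested ramp is censored,
#' never extrapolated: `below_range` when even the most extreme tested
#' cycle length behaves normally, `above_range` when the endpoint is
#' already present at the longest cycle length tested.
#'
#' @param log A `stim_log`.
#' @param endpoint One of `"wenckebach"`, `"two_to_one"`, `"retrograde"`.
#' @return An `ep_value` (ms).
#' @export
find_conduction_cl <- function(log, endpoint = c("wenckebach", "two_to_one",
                                                 "retrograde")) {
  stopifnot(inherits(log, "stim_log"))
  endpoint <- match.arg(endpoint)
  ev <- log$events
  type <- if (endpoint == "retrograde") "va_ramp" else "avn_ramp"
  resp_chamber <- if (endpoint == "retrograde") "atrium" else "ventricle"
  ids <- unique(ev$maneuver_id[ev$maneuver_type == type])
  if (!length(ids)) stop_not_evaluable("no pacing ramp of the required kind")
  per_cl <- do.call(rbind, lapply(ids, function(id) {
    stim <- ev[ev$maneuver_id == id & ev$kind == "stimulus", ]
    resp <- ev[ev$maneuver_id == id & ev$kind == "sense" &
                 ev$label == "conducted_response" &
                 ev$chamber == resp_chamber, ]
    data.frame(cl = median(diff(sort(stim$time))),
               ratio = nrow(resp) / nrow(stim))
  }))
  per_cl <- per_cl[order(per_cl$cl), ]
  hit <- switch(endpoint,
    wenckebach = per_cl$ratio < 0.999,
    two_to_one = abs(per_cl$ratio - 0.5) < 0.06,
    retrograde = per_cl$ratio == 0
  )
  if (!any(hit)) return(ep_value(NA_real_, censored = "below_range"))
  v <- max(per_cl$cl[hit])
  if (v >= max(per_cl$cl)) return(ep_value(NA_real_, censored = "above_range"))
  ep_value(v)
}

#' Effective refractory period from an S1/S2 scan
#'
#' ERP is the longest S1-S2 coupling interval whose extra stimulus fails:
#' fails to capture for atrium and ventricle, or captures the atrium but
#' fails to conduct to the ventricle for the AV node. A non-monotonic scan
#' (a failure above a success) still resolves to the longest failing
#' coupling, with a warning. Scans in which no coupling fails — or in
#' which every coupling fails — are censored below or above the tested
#' range.
#'
#' @param log A `stim_log`.
#' @param tissue `"atrium"`, `"ventricle"` or `"av_node"`.
#' @param drive_cl Drive-train cycle length of the scan, ms.
#' @return An `ep_value` (ms).
#' @export
compute_erp <- function(log, tissue = c("atrium", "ventricle", "av_node"),
                        drive_cl) {
  stopifnot(inherits(log, "stim_log"))
  tissue <- match.arg(tissue)
  ev <- log$events
  prot <- log$protocol
  ids <- prot$maneuver_id[prot$type == "erp" & prot$tissue == tissue &
                            prot$drive_cl == drive_cl]
  if (!length(ids)) stop_not_evaluable("no S1/S2 scan for this tissue and drive CL")
  scan <- do.call(rbind, lapply(ids, function(id) {
    me <- ev[ev$maneuver_id == id, ]
    cp <- me$coupling[me$label == "S2"][1]
    cap_chamber <- if (tissue == "ventricle") "ventricle" else "atrium"
    captured <- any(me$kind == "sense" & me$label == "capture" &
                      me$chamber == cap_chamber)
    success <- if (tissue == "av_node") {
      captured && any(me$kind == "sense" & me$label == "conducted_response" &
                        me$chamber == "ventricle")
    } else {
      captured
    }
    informative <- if (tissue == "av_node") captured else TRUE
    data.frame(coupling = cp, success = success, informative = informative)
  }))
  scan <- scan[scan$informative, , drop = FALSE]
  if (!nrow(scan)) {
    return(ep_value(NA_real_, censored = "below_range",
                    note = "no informative coupling"))
  }
  scan <- scan[order(scan$coupling), ]
  fails <- !scan$success
  if (!any(fails)) return(ep_value(NA_real_, censored = "below_range"))
  if (all(fails)) return(ep_value(NA_real_, censored = "above_range"))
  erp <- max(scan$coupling[fails])
  if (any(scan$success & scan$coupling < erp)) {
    warning("non-monotonic S1/S2 scan: resolving to the longest failing coupling")
  }
  ep_value(erp)
}

#' Induced arrhythmia episodes after stimulation maneuvers
#'
#' An atrial episode is a span of rapid ectopic atrial activity after a
#' maneuver lasting at least 3 s; a ventricular episode is a run of four
#' or more consecutive ventricular beats after stimulation. Episodes are
#' linked to the maneuver that induced them.
#'
#' @param log A `stim_log`.
#' @param chamber `"atrium"` or `"ventricle"`.
#' @param min_atrial_s Atrial qualification bound, s.
#' @param min_ventricular_beats Ventricular qualification bound, beats.
#' @return Tibble: `maneuver_id`, `chamber`, `onset`, `offset`,
#'   `duration_s`, `n_beats`.
#' @export
detect_induced_episodes <- function(log, chamber = c("atrium", "ventricle"),
                                    min_atrial_s = 3,
                                    min_ventricular_beats = 4) {
  stopifnot(inherits(log, "stim_log"))
  chamber <- match.arg(chamber)
  label <- if (chamber == "atrium") "atrial_ectopic" else "ventricular_ectopic"
  ev <- log$events
  ect <- ev[ev$kind == "sense" & ev$label == label & ev$chamber == chamber, ]
  empty <- tibble::tibble(maneuver_id = integer(), chamber = character(),
                          onset = numeric(), offset = numeric(),
                          duration_s = numeric(), n_beats = integer())
  if (!nrow(ect)) return(empty)
  out <- do.call(rbind, lapply(split(ect, ect$maneuver_id), function(d) {
    span <- max(d$time) - min(d$time)
    ok <- if (chamber == "atrium") {
      span >= min_atrial_s * 1000
    } else {
      nrow(d) >= min_ventricular_beats
    }
    if (!ok) return(NULL)
    data.frame(maneuver_id = d$maneuver_id[1], chamber = chamber,
               onset = min(d$time), offset = max(d$time),
               duration_s = span / 1000, n_beats = nrow(d))
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$onset), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Inducibility and arrhythmia burden
#'
#' Inducibility is the number of successful stimulation maneuvers (those
#' with at least one linked qualifying episode) over all stimulation
#' maneuvers for the chamber; burden is the summed episode duration.
#'
#' @param episodes Episode table from [detect_induced_episodes()].
#' @param log The `stim_log` the episodes came from (supplies the
#'   maneuver roster).
#' @param chamber `"atrium"` or `"ventricle"`.
#' @return One-row tibble: `chamber`, `n_success`, `n_maneuvers`,
#'   `inducibility_pct`, `mean_episode_s`, `burden_s`.
#' @export
inducibility_and_burden <- function(episodes, log,
                                    chamber = c("atrium", "ventricle")) {
  stopifnot(inherits(log, "stim_log"))
  chamber <- match.arg(chamber)
  prot <- log$protocol
  roster <- prot$maneuver_id[prot$type %in% c("induction", "burst") &
                               prot$chamber == chamber]
  if (!length(roster)) stop("empty maneuver roster for this chamber")
  ep <- episodes[episodes$chamber == chamber, , drop = FALSE]
  n_success <- length(intersect(roster, unique(ep$maneuver_id)))
  tibble::tibble(
    chamber = chamber,
    n_success = n_success,
    n_maneuvers = length(roster),
    inducibility_pct = 100 * n_success / length(roster),
    mean_episode_s = if (nrow(ep)) mean(ep$duration_s) else 0,
    burden_s = sum(ep$duration_s)
  )
}

#' Full EP parameter panel for one animal's log
#'
#' @param log A `stim_log`.
#' @param drive_cls Drive cycle lengths present in the protocol.
#' @return Long tibble: `parameter`, `drive_cl`, `value`, `censored`.
#' @export
analyze_ep <- function(log, drive_cls = c(120, 100)) {
  rows <- list()
  push <- function(parameter, drive_cl, v) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, drive_cl = drive_cl,
      value = v$value, censored = v$censored
    )
  }
  for (d in drive_cls) push("snrt_corrected", d, compute_snrt(log, d))
  push("wb_cl", NA, find_conduction_cl(log, "wenckebach"))
  push("two_to_one_cl", NA, find_conduction_cl(log, "two_to_one"))
  push("va_cl", NA, find_conduction_cl(log, "retrograde"))
  for (tis in c("atrium", "av_node", "ventricle")) {
    nm <- c(atrium = "aerp", av_node = "averp", ventricle = "verp")[[tis]]
    for (d in drive_cls) push(nm, d, compute_erp(log, tis, d))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Cohort-level inducibility and burden summary
#'
#' Aggregates per-animal inducibility results: cohort inducibility pools
#' maneuvers across animals; total burden is the exact sum of per-animal
#' burdens. Burden per animal is reported both over all animals and over
#' inducible animals only, since the two denominators answer different
#' questions.
#'
#' @param per_animal Tibble binding [inducibility_and_burden()] rows with a
#'   `subject_id` column.
#' @return One-row tibble per chamber with cohort totals.
#' @export
cohort_inducibility <- function(per_animal) {
  do.call(rbind, lapply(split(per_animal, per_animal$chamber), function(d) {
    inducible <- d$n_success > 0
    tibble::tibble(
      chamber = d$chamber[1],
      n_animals = nrow(d),
      n_success = sum(d$n_success),
      n_maneuvers = sum(d$n_maneuvers),
      inducibility_pct = 100 * sum(d$n_success) / sum(d$n_maneuvers),
      total_burden_s = sum(d$burden_s),
      burden_per_animal_s = sum(d$burden_s) / nrow(d),
      burden_per_inducible_animal_s =
        if (any(inducible)) sum(d$burden_s) / sum(inducible) else 0
    )
  }))
}
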