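new_episode_table <- function(kind = character(), onset = numeric(),
                              offset = numeric(), n_beats = integer()) {
  tibble::tibble(kind = kind, onset = onset, offset = offset,
                 n_beats = as.integer(n_beats))
}

# RR stream between consecutive conducted sinus beats; an interval is valid
# only if no other event (non-conducted P, ventricular or fusion beat)
# intervenes, so pauses caused by AV block are never attributed to sinus
# irregularity.
sinus_rr_stream <- function(fid) {
  si <- which(fid$class == "sinus" & (is.na(fid$conducted) | fid$conducted) &
                !is.na(fid$r_peak))
  if (length(si) < 2) {
    return(data.frame(t0 = numeric(), t1 = numeric(), rr = numeric()))
  }
  a <- si[-length(si)]
  b <- si[-1]
  valid <- b == a + 1L
  data.frame(t0 = fid$r_peak[a][valid], t1 = fid$r_peak[b][valid],
             rr = (fid$r_peak[b] - fid$r_peak[a])[valid])
}

#' Detect sinus arrhythmia as sustained RR irregularity
#'
#' Operationalizes the visual call of "visibly irregular sinus rhythm" as a
#' sliding-window criterion: among conducted sinus beats, any
#' `window_beats`-interval window whose coefficient of variation of RR
#' exceeds `cv_threshold` is flagged; overlapping flagged windows merge
#' into episodes. Intervals interrupted by non-conducted P waves or
#' ventricular beats are excluded first, so block-induced pauses do not
#' masquerade as sinus arrhythmia. The threshold is a package-defined
#' operationalization, not a value stated by any reference analysis.
#'
#' @param fiducials A `beat_fiducials` table.
#' @param cv_threshold Coefficient-of-variation threshold (default 0.15).
#' @param window_beats Sliding window length in intervals (default 10).
#' @return Episode tibble (`kind = "sinus_arrhythmia"`).
#' @export
detect_sinus_arrhythmia <- function(fiducials, cv_threshold = 0.15,
                                    window_beats = 10) {
  fid <- fiducials
  n_sinus <- sum(fid$class == "sinus" & (is.na(fid$conducted) | fid$conducted))
  if (n_sinus < 30) {
    stop_insufficient_data("sinus arrhythmia screening needs at least 30 sinus beats")
  }
  st <- sinus_rr_stream(fid)
  n <- nrow(st)
  if (n < window_beats) return(new_episode_table())
  # windows of `window_beats` consecutive valid intervals; a window is
  # usable only when its intervals are contiguous in time
  flagged <- rep(FALSE, n - window_beats + 1)
  for (i in seq_along(flagged)) {
    w <- i:(i + window_beats - 1)
    if (any(st$t0[w[-1]] != st$t1[w[-length(w)]])) next
    cv <- sd(st$rr[w]) / mean(st$rr[w])
    flagged[i] <- is.finite(cv) && cv > cv_threshold
  }
  runs <- true_runs(flagged)
  if (!nrow(runs)) return(new_episode_table())
  new_episode_table(
    kind = rep("sinus_arrhythmia", nrow(runs)),
    onset = st$t0[runs$start],
    offset = st$t1[runs$end + window_beats - 1],
    n_beats = runs$end + window_beats - runs$start + 1L
  )
}

#' Detect atrioventricular block episodes
#'
#' From the atrial event stream (all beats carrying a P wave, conducted or
#' not), classifies: `avb2_wenckebach` — a run of two or more conducted
#' beats with strictly increasing PR immediately followed by exactly one
#' non-conducted P, with conduction resuming afterwards; `avb3` — two or
#' more consecutive non-conducted P waves (intermittent complete block).
#' Each non-conducted P belongs to at most one episode, so the two episode
#' sets are disjoint by construction. A single isolated dropped P without
#' preceding PR prolongation is counted under neither subtype by default.
#'
#' @param fiducials A `beat_fiducials` table; P annotations must exist.
#' @param min_pr_increment Minimum PR increase per beat to count as
#'   prolonging, ms (tolerance for measurement noise).
#' @param include_unspecified If `TRUE`, isolated dropped P waves without
#'   PR prolongation are returned as kind `"avb_unspecified"`.
#' @return Episode tibble with kinds `avb2_wenckebach` / `avb3`.
#' @export
detect_av_block <- function(fiducials, min_pr_increment = 3,
                            include_unspecified = FALSE) {
  fid <- fiducials
  atr <- fid[!is.na(fid$p_onset) & fid$class %in% c("sinus", "atrial"), ]
  if (!nrow(atr)) {
    stop_not_evaluable("no atrial (P wave) annotations: AV block not evaluable")
  }
  atr <- atr[order(atr$p_onset), ]
  conducted <- !is.na(atr$conducted) & atr$conducted
  episodes <- new_episode_table()
  runs <- true_runs(!conducted)
  if (!nrow(runs)) return(episodes)
  for (k in seq_len(nrow(runs))) {
    a <- runs$start[k]
    b <- runs$end[k]
    len <- b - a + 1L
    if (len >= 2L) {
      episodes <- rbind(episodes, new_episode_table(
        "avb3", atr$p_onset[a], atr$p_offset[b], len
      ))
    } else {
      # single dropped P: Wenckebach if preceded by >= 2 conducted beats
      # with strictly increasing PR and followed by resumed conduction
      resumed <- b < nrow(atr) && conducted[b + 1]
      j <- a - 1L
      while (j > 1L && conducted[j] && conducted[j - 1L] &&
             !is.na(atr$pr[j]) && !is.na(atr$pr[j - 1L]) &&
             atr$pr[j] - atr$pr[j - 1L] > min_pr_increment) {
        j <- j - 1L
      }
      n_inc <- a - j            # conducted beats in the prolonging run
      if (resumed && n_inc >= 2L) {
        episodes <- rbind(episodes, new_episode_table(
          "avb2_wenckebach", atr$p_onset[j], atr$p_offset[a], n_inc + 1L
        ))
      } else if (include_unspecified) {
        episodes <- rbind(episodes, new_episode_table(
          "avb_unspecified", atr$p_onset[a], atr$p_offset[a], 1L
        ))
      }
    }
  }
  episodes
}

#' Detect abnormal spontaneous ventricular activity
#'
#' Maximal runs of consecutive ventricular-class beats of length
#' `min_run` or more (default 4, the definition of abnormal spontaneous
#' ventricular activity) become episodes. Fusion beats are transparent:
#' they neither break a run nor count towards its length.
#'
#' @param fiducials A `beat_fiducials` table with beat classes assigned.
#' @param min_run Minimum consecutive ventricular beats (default 4).
#' @return Episode tibble (`kind = "ventricular_activity"`).
#' @export
detect_ventricular_activity <- function(fiducials, min_run = 4) {
  fid <- fiducials[!is.na(fiducials$r_peak), ]
  episodes <- new_episode_table()
  run_rows <- integer(0)
  flush <- function() {
    if (length(run_rows) >= min_run) {
      last <- run_rows[length(run_rows)]
      off <- fid$t_end[last]
      if (is.na(off)) off <- fid$qrs_offset[last]
      episodes <<- rbind(episodes, new_episode_table(
        "ventricular_activity", fid$qrs_onset[run_rows[1]], off,
        length(run_rows)
      ))
    }
    run_rows <<- integer(0)
  }
  for (i in seq_len(nrow(fid))) {
    cls <- fid$class[i]
    if (cls == "ventricular") {
      run_rows <- c(run_rows, i)
    } else if (cls == "fusion") {
      next              # transparent
    } else {
      flush()
    }
  }
  flush()
  episodes
}

#' Run all rhythm detectors on one record
#'
#' @param fiducials A `beat_fiducials` table.
#' @param subject_id,group Labels attached to the result.
#' @param cv_threshold Passed to [detect_sinus_arrhythmia()].
#' @return An object of class `rhythm_findings`: list with `subject_id`,
#'   `group`, `episodes` (tibble) and `flags` (named logical, one per
#'   kind; a flag is `TRUE` iff at least one episode of that kind exists,
#'   `NA` when the detector was not evaluable).
#' @export
rhythm_findings <- function(fiducials, subject_id = NA_character_,
                            group = NA_character_, cv_threshold = 0.15) {
  kinds <- c("sinus_arrhythmia", "avb2_wenckebach", "avb3",
             "ventricular_activity")
  run <- function(expr) {
    tryCatch(expr, error = function(e) NULL)
  }
  sa <- run(detect_sinus_arrhythmia(fiducials, cv_threshold = cv_threshold))
  avb <- run(detect_av_block(fiducials))
  va <- run(detect_ventricular_activity(fiducials))
  episodes <- rbind(sa %||% new_episode_table(),
                    avb %||% new_episode_table(),
                    va %||% new_episode_table())
  flags <- setNames(rep(NA, length(kinds)), kinds)
  if (!is.null(sa)) flags["sinus_arrhythmia"] <- any(sa$kind == "sinus_arrhythmia")
  if (!is.null(avb)) {
    flags["avb2_wenckebach"] <- any(avb$kind == "avb2_wenckebach")
    flags["avb3"] <- any(avb$kind == "avb3")
  }
  if (!is.null(va)) flags["ventricular_activity"] <- any(va$kind == "ventricular_activity")
  structure(list(subject_id = subject_id, group = group,
                 episodes = episodes, flags = flags),
            class = "rhythm_findings")
}

#' @export
print.rhythm_findings <- function(x, ...) {
  cat(sprintf("<rhythm_findings> subject %s (%s): %d episode(s); flags: %s\n",
              x$subject_id, x$group, nrow(x$episodes),
              paste(names(x$flags)[which(x$flags)], collapse = ", ")))
  invisible(x)
}

#' Per-group arrhythmia prevalence
#'
#' Fraction of animals per group with at least one episode of each kind —
#' the quantity compared across narcosis groups by the chi-square test.
#'
#' @param findings A list of [rhythm_findings()] objects.
#' @return Tibble with `group`, `kind`, `n_flagged`, `n_animals`, `pct`.
#' @export
summarize_prevalence <- function(findings) {
  stopifnot(length(findings) >= 1)
  rows <- do.call(rbind, lapply(findings, function(f) {
    data.frame(group = f$group, kind = names(f$flags),
               flagged = as.logical(f$flags))
  }))
  out <- do.call(rbind, lapply(split(rows, list(rows$group, rows$kind),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], kind = d$kind[1],
               n_flagged = sum(d$flagged, na.rm = TRUE),
               n_animals = nrow(d))
  }))
  if (any(out$n_animals == 0)) stop("empty group")
  out$pct <- 100 * out$n_flagged / out$n_animals
  out <- out[order(out$kind, out$group), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
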