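#' Configuration of a synthetic three-group study
#'
#' Defines the cohort (awake controls plus the two narcosis regimens),
#' record lengths, sampling rate, detector thresholds and the master seed
#' from which every per-animal seed is derived. The defaults mirror the
#' study design the package emulates: 7 awake, 10 MMF and 12 IF animals,
#' 5-minute tachograms for HRV, and a delineated surface-ECG segment per
#' animal.
#'
#' @param seed Master seed (integer).
#' @param groups Data frame with columns `group`
#'   (`"awake"`/`"mmf"`/`"if"`) and `n`.
#' @param rr_duration_s Tachogram length for HRV analysis, s.
#' @param ecg_duration_s Rendered ECG segment length, s.
#' @param sampling_rate ECG sampling rate, Hz.
#' @param include_ep Run the invasive EP simulation for the narcosis
#'   groups.
#' @param cv_threshold Sinus-arrhythmia irregularity criterion.
#' @param prr_threshold_ms pRR threshold, ms.
#' @param qtc_rr0 Mitchell QTc normalization RR, ms.
#' @return Object of class `study_config`.
#' @export
study_config <- function(seed = 20230323,
                         groups = data.frame(group = c("awake", "mmf", "if"),
                                             n = c(7L, 10L, 12L)),
                         rr_duration_s = 300,
                         ecg_duration_s = 30,
                         sampling_rate = 2000,
                         include_ep = TRUE,
                         cv_threshold = 0.15,
                         prr_threshold_ms = 50,
                         qtc_rr0 = 100) {
  stopifnot(all(c("group", "n") %in% names(groups)),
            all(groups$group %in% c("awake", "mmf", "if")),
            all(groups$n >= 1))
  structure(list(seed = as.integer(seed), groups = groups,
                 rr_duration_s = rr_duration_s,
                 ecg_duration_s = ecg_duration_s,
                 sampling_rate = sampling_rate, include_ep = include_ep,
                 cv_threshold = cv_threshold,
                 prr_threshold_ms = prr_threshold_ms, qtc_rr0 = qtc_rr0),
            class = "study_config")
}

#' Read or write a study configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [study_config()].
#' @return `read_study_config()` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$groups <- as.data.frame(y$groups)
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- unclass(config)
  y$groups <- as.list(as.data.frame(config$groups))
  yaml::write_yaml(y, path)
  invisible(path)
}

# group-specific surface-ECG conduction parameters; the common QTc of
# 35 ms reflects unchanged ventricular repolarization across groups
group_ecg_params <- function(group, mean_rr) {
  p <- switch(group,
    awake = list(pr = 38.05, p_dur = 11.65, qrs = 10),
    mmf = list(pr = 54.01, p_dur = 18.74, qrs = 10),
    `if` = list(pr = 44.43, p_dur = 12.16, qrs = 10)
  )
  p$qt <- 35 * sqrt(mean_rr / 100)
  p
}

# preset used for the rendered ECG segment: for MMF the respiratory HF
# amplitude is damped so baseline modulation stays below the
# sinus-arrhythmia criterion and prevalence is governed by the injection
# roster (the visual arrhythmia call is a discrete finding)
ecg_render_preset <- function(group, seed) {
  if (group == "mmf") {
    autonomic_preset("mmf", hf_amp = 0.12, seed = seed)
  } else {
    autonomic_preset(group, seed = seed)
  }
}

# MMF disorder roster mirroring the observed prevalences: sinus
# arrhythmia in 9/10, high-grade AV block (Wenckebach + intermittent
# third-degree) in 5/10, ventricular runs in 3/10
mmf_roster <- function(i, n) {
  list(
    sinus_arrhythmia = i <= round(0.9 * n),
    av_block = i <= round(0.5 * n),
    ventricular_run = i <= round(0.3 * n)
  )
}

inject_mmf_disorders <- function(truth, roster, pr) {
  nb <- nrow(truth$events)
  if (roster$sinus_arrhythmia && nb >= 60) {
    truth <- inject_conduction_disorder(truth, "sinus_arrhythmia",
                                        start = 15, n_beats = 40)
  }
  if (roster$av_block && nb >= 95) {
    truth <- inject_conduction_disorder(truth, "wenckebach", start = 62,
                                        k = 3, n_cycles = 2,
                                        pr_start = pr + 2, pr_increment = 8)
    truth <- inject_conduction_disorder(truth, "intermittent_avb3",
                                        start = 78, run_length = 2,
                                        n_runs = 2, gap_beats = 6)
  }
  if (roster$ventricular_run && nb >= 110) {
    truth <- inject_conduction_disorder(truth, "ventricular_run",
                                        start = 100, run_length = 5)
  }
  truth
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))))
}

#' Run the full synthetic study pipeline
#'
#' Simulates the cohort defined by the configuration and pushes every
#' animal through the complete analysis chain: tachogram generation and
#' HRV panel, ECG rendering with roster-driven disorder injection,
#' R detection, delineation and interval measurement, rhythm-disorder
#' detection and prevalence, virtual-heart EP study with parameter
#' extraction and inducibility, and the group-statistics layer (one-way
#' ANOVA with Tukey pairs across the three groups, normality-gated
#' two-group tests for EP parameters, chi-square for proportions). The
#' run is bit-reproducible for a fixed configuration.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, all result tables and
#'   the manifest are written there as CSV/JSON.
#' @return Object of class `study_results`: list of tibbles (`hrv`,
#'   `ecg_intervals`, `episodes`, `prevalence`, `ep_parameters`,
#'   `inducibility_animal`, `inducibility_cohort`, `comparisons`,
#'   `stage_status`) plus the run `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  hrv_rows <- list(); ecg_rows <- list(); findings <- list()
  episode_rows <- list(); ep_rows <- list(); ind_rows <- list()
  status <- list()
  note_status <- function(stage, subject, ok, msg = "") {
    status[[length(status) + 1L]] <<- data.frame(
      stage = stage, subject_id = subject, ok = ok, message = msg
    )
  }

  gi <- 0L
  for (g in seq_len(nrow(config$groups))) {
    group <- config$groups$group[g]
    n <- config$groups$n[g]
    for (i in seq_len(n)) {
      gi <- gi + 1L
      subject <- sprintf("%s_%02d", group, i)
      seed_a <- config$seed + 1000L * g + i

      # --- HRV from the long tachogram -------------------------------
      res <- tryCatch({
        preset <- autonomic_preset(group, seed = seed_a)
        rr <- generate_rr_series(preset, config$rr_duration_s)
        panel <- hrv_panel(rr, threshold_ms = config$prr_threshold_ms)
        hrv_rows[[gi]] <- cbind(
          data.frame(subject_id = subject, group = group), panel
        )
        TRUE
      }, error = function(e) conditionMessage(e))
      note_status("hrv", subject, isTRUE(res),
                  if (!isTRUE(res)) res else "")

      # --- surface ECG: render, delineate, measure, detect ------------
      res <- tryCatch({
        ep_seed <- seed_a + 500000L
        rr_e <- generate_rr_series(ecg_render_preset(group, ep_seed),
                                   config$ecg_duration_s)
        gp <- group_ecg_params(group, mean(rr_e$rr))
        truth <- synth_truth(rr_e, pr = gp$pr, p_dur = gp$p_dur,
                             qrs_dur = gp$qrs, qt = gp$qt)
        if (group == "mmf") {
          truth <- inject_mmf_disorders(truth, mmf_roster(i, n), gp$pr)
        }
        sim <- synthesize_ecg(truth, sampling_rate = config$sampling_rate,
                              subject_id = subject, group = group)
        fid <- delineate_beats(sim$signal, detect_r_peaks(sim$signal),
                               truth = truth)
        iv <- measure_intervals(fid, qtc_rr0 = config$qtc_rr0)
        ecg_rows[[gi]] <- cbind(
          data.frame(subject_id = subject, group = group), iv
        )
        f <- rhythm_findings(fid, subject_id = subject, group = group,
                             cv_threshold = config$cv_threshold)
        findings[[gi]] <- f
        if (nrow(f$episodes)) {
          episode_rows[[gi]] <- cbind(
            data.frame(subject_id = subject, group = group), f$episodes
          )
        }
        TRUE
      }, error = function(e) conditionMessage(e))
      note_status("ecg", subject, isTRUE(res),
                  if (!isTRUE(res)) res else "")

      # --- invasive EP study (narcosis groups only) -------------------
      if (config$include_ep && group != "awake") {
        res <- tryCatch({
          heart <- virtual_heart_preset(group, seed = seed_a + 900000L)
          log <- simulate_ep_responses(heart)
          pars <- analyze_ep(log)
          ep_rows[[gi]] <- cbind(
            data.frame(subject_id = subject, group = group), pars
          )
          ind <- rbind(
            inducibility_and_burden(
              detect_induced_episodes(log, "atrium"), log, "atrium"),
            inducibility_and_burden(
              detect_induced_episodes(log, "ventricle"), log, "ventricle")
          )
          ind_rows[[gi]] <- cbind(
            data.frame(subject_id = subject, group = group), ind
          )
          TRUE
        }, error = function(e) conditionMessage(e))
        note_status("ep", subject, isTRUE(res),
                    if (!isTRUE(res)) res else "")
      }
    }
  }

  hrv <- tibble::as_tibble(do.call(rbind, hrv_rows))
  ecg <- tibble::as_tibble(do.call(rbind, ecg_rows))
  episodes <- if (length(episode_rows)) {
    tibble::as_tibble(do.call(rbind, episode_rows))
  } else {
    tibble::tibble(subject_id = character(), group = character(),
                   kind = character(), onset = numeric(),
                   offset = numeric(), n_beats = integer())
  }
  prevalence <- summarize_prevalence(findings)
  ep_parameters <- if (length(ep_rows)) {
    tibble::as_tibble(do.call(rbind, ep_rows))
  } else NULL
  ind_animal <- if (length(ind_rows)) {
    tibble::as_tibble(do.call(rbind, ind_rows))
  } else NULL
  ind_cohort <- if (!is.null(ind_animal)) {
    do.call(rbind, lapply(split(ind_animal, ind_animal$group), function(d) {
      cbind(data.frame(group = d$group[1]), cohort_inducibility(d))
    }))
  } else NULL

  comparisons <- study_comparisons(hrv, ecg, prevalence, ep_parameters,
                                   ind_animal)

  manifest <- list(
    package = "murineEP",
    version = as.character(utils::packageVersion("murineEP")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)), "groups")],
    groups = as.data.frame(config$groups)
  )

  results <- structure(list(
    hrv = hrv, ecg_intervals = ecg, episodes = episodes,
    prevalence = prevalence, ep_parameters = ep_parameters,
    inducibility_animal = ind_animal,
    inducibility_cohort = if (!is.null(ind_cohort)) {
      tibble::as_tibble(ind_cohort)
    } else NULL,
    comparisons = comparisons,
    stage_status = tibble::as_tibble(do.call(rbind, status)),
    manifest = manifest
  ), class = "study_results")
  if (!is.null(out_dir)) write_results_bundle(results, out_dir)
  results
}

# assemble the tidy comparison table across all derived parameters
study_comparisons <- function(hrv, ecg, prevalence, ep_parameters,
                              ind_animal) {
  rows <- list()
  push <- function(parameter, comparison, cr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, comparison = comparison,
      test = cr$test_used, statistic = cr$statistic, p_value = cr$p_value,
      stars = significance_stars(cr$p_value)
    )
  }
  three_way <- function(df, params) {
    for (p in params) {
      gl <- split(df[[p]], df$group)[c("awake", "mmf", "if")]
      cr <- tryCatch(compare_three(gl), error = function(e) NULL)
      if (!is.null(cr)) push(p, "awake_vs_mmf_vs_if", cr)
    }
  }
  three_way(hrv, c("median_rr", "sdrr", "rmssd", "prr50", "vlf_pct",
                   "lf_pct", "hf_pct", "lf_hf", "sd1", "sd2"))
  three_way(ecg, c("heart_rate", "pr", "p_duration", "qrs", "qtc"))
  if (!is.null(ep_parameters)) {
    key <- paste0(ep_parameters$parameter,
                  ifelse(is.na(ep_parameters$drive_cl), "",
                         paste0("_", ep_parameters$drive_cl)))
    for (k in unique(key)) {
      d <- ep_parameters[key == k & is.na(ep_parameters$censored), ]
      cr <- tryCatch(
        compare_two(d$value[d$group == "mmf"], d$value[d$group == "if"]),
        error = function(e) NULL
      )
      if (!is.null(cr)) push(k, "mmf_vs_if", cr)
    }
  }
  for (kind in unique(prevalence$kind)) {
    d <- prevalence[prevalence$kind == kind, ]
    cr <- tryCatch(
      compare_proportions(d$n_flagged, d$n_animals),
      error = function(e) NULL
    )
    if (!is.null(cr)) push(paste0("prevalence_", kind), "all_groups", cr)
  }
  if (!is.null(ind_animal)) {
    for (ch in unique(ind_animal$chamber)) {
      d <- ind_animal[ind_animal$chamber == ch, ]
      agg_s <- tapply(d$n_success, d$group, sum)
      agg_n <- tapply(d$n_maneuvers, d$group, sum)
      cr <- tryCatch(
        compare_proportions(as.integer(agg_s), as.integer(agg_n)),
        error = function(e) NULL
      )
      if (!is.null(cr)) push(paste0("inducibility_", ch), "mmf_vs_if", cr)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf(
    "<study_results> %d animals; %d comparisons; %d detected episode(s)\n",
    nrow(x$hrv), nrow(x$comparisons), nrow(x$episodes)
  ))
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Each table becomes a CSV; the manifest (configuration, seeds, package
#' version) is written as JSON so a run can be reproduced from the bundle
#' alone.
#'
#' @param results A `study_results`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_results_bundle <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("hrv", "ecg_intervals", "episodes", "prevalence",
               "ep_parameters", "inducibility_animal",
               "inducibility_cohort", "comparisons", "stage_status")) {
    tb <- results[[nm]]
    if (is.null(tb)) next
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tb), f, row.names = FALSE)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
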