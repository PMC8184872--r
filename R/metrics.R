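#' Trial-metric parameters
#'
#' @param srt_min_ms Minimum plausible saccadic reaction time, ms; earlier
#'   large saccades are anticipations.
#' @param direction_check Require the response saccade's direction to match
#'   the cued direction.
#' @param error_round_deg Quantum for rounding subject-average saccadic
#'   error (0.03 degrees, one pixel's worth at the recording geometry).
#' @param target_ecc_deg Horizontal target eccentricity, degrees.
#' @param subject_missing_exclusion_frac Subjects whose overall fraction of
#'   missing samples exceeds this are excluded (poor data quality).
#' @return A list of class `metrics_params`.
#' @export
metrics_params <- function(srt_min_ms = 80, direction_check = TRUE,
                           error_round_deg = 0.03, target_ecc_deg = 12,
                           subject_missing_exclusion_frac = 0.3) {
  if (srt_min_ms < 0) stop_config("srt_min_ms must be non-negative")
  if (error_round_deg <= 0) stop_config("error_round_deg must be positive")
  structure(list(srt_min_ms = srt_min_ms,
                 direction_check = isTRUE(direction_check),
                 error_round_deg = error_round_deg,
                 target_ecc_deg = target_ecc_deg,
                 subject_missing_exclusion_frac =
                   subject_missing_exclusion_frac),
            class = "metrics_params")
}

# Core response-saccade selection for one trial, on plain event vectors.
# Returns list(idx = selected event index or NA, status, srt_ms).
select_response_core <- function(onset_ms, direction, is_large,
                                 cue_on_ms, trial_end_ms, cue_direction,
                                 p, any_blink = FALSE) {
  cand <- which(is_large & onset_ms > cue_on_ms & onset_ms < trial_end_ms)
  if (length(cand) == 0) {
    status <- if (any_blink) "blink_contaminated" else "no_saccade"
    return(list(idx = NA_integer_, status = status, srt_ms = NA_real_))
  }
  cand <- cand[order(onset_ms[cand])]
  saw_anticipatory <- FALSE
  saw_wrong_dir <- FALSE
  for (r in cand) {
    srt <- onset_ms[r] - cue_on_ms
    if (srt < p$srt_min_ms) {
      saw_anticipatory <- TRUE
      next
    }
    if (p$direction_check && !is.na(direction[r]) &&
        direction[r] != cue_direction) {
      saw_wrong_dir <- TRUE
      next
    }
    return(list(idx = r, status = "valid", srt_ms = srt))
  }
  status <- if (saw_anticipatory) "anticipatory"
  else if (saw_wrong_dir) "wrong_direction"
  else if (any_blink) "blink_contaminated" else "no_saccade"
  list(idx = NA_integer_, status = status, srt_ms = NA_real_)
}

#' Select the response saccade for one trial
#'
#' The response saccade is the first large (peak velocity above the big
#' threshold) event with onset after the cue and before trial end, latency
#' of at least `srt_min_ms`, and (optionally) direction matching the cue.
#'
#' @param events Event tibble from [detect_saccades()] for one trial.
#' @param spec The trial's schedule row.
#' @param p [metrics_params()].
#' @param any_blink Whether a blink interval overlaps the response window
#'   (used to label saccade-less trials).
#' @return A list with `event` (one-row tibble or `NULL`), `status`, and
#'   `srt_ms`.
#' @export
select_response_saccade <- function(events, spec, p = metrics_params(),
                                    any_blink = FALSE) {
  if (is.null(events) || nrow(events) == 0) {
    sel <- select_response_core(numeric(0), character(0), logical(0),
                                spec$cue_on_ms, spec$trial_end_ms,
                                spec$direction, p, any_blink)
  } else {
    sel <- select_response_core(events$onset_ms, events$direction,
                                events$is_large, spec$cue_on_ms,
                                spec$trial_end_ms, spec$direction, p,
                                any_blink)
  }
  list(event = if (is.na(sel$idx)) NULL else events[sel$idx, ],
       status = sel$status, srt_ms = sel$srt_ms)
}

#' Saccadic error: landing-to-target distance
#'
#' Euclidean distance in degrees between the landing point and the target
#' cross at (+/- `target_ecc_deg`, 0); targets sit on the horizontal axis
#' for every orientation condition.
#'
#' @param landing_x,landing_y Landing point, degrees.
#' @param direction `"left"` or `"right"` (selects the target).
#' @param p [metrics_params()].
#' @return Error in degrees (vectorised).
#' @export
compute_error <- function(landing_x, landing_y, direction,
                          p = metrics_params()) {
  tx <- ifelse(direction == "right", p$target_ecc_deg, -p$target_ecc_deg)
  sqrt((landing_x - tx)^2 + landing_y^2)
}

#' Per-trial results: SRT, saccadic error, and status
#'
#' Joins detected events to the schedule and classifies every trial:
#' `valid` (response saccade found), `anticipatory`, `wrong_direction`,
#' `blink_contaminated`, `no_saccade`, or `red_excluded` (catch trials,
#' never analysed). Every trial receives exactly one status.
#'
#' @param events Event tibble from [detect_saccades()] (all trials).
#' @param schedule Schedule tibble.
#' @param p [metrics_params()].
#' @param blink_trials Optional vector of trial ids whose response window
#'   contains a blink.
#' @return Tibble: one row per trial with design columns, `srt_ms`,
#'   `error_deg`, `status`.
#' @export
trial_results <- function(events, schedule, p = metrics_params(),
                          blink_trials = integer(0)) {
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    spec <- schedule[i, ]
    base <- tibble::tibble(
      trial_id = spec$trial_id, tool_end = spec$tool_end,
      orientation = spec$orientation, soa_ms = spec$soa_ms,
      direction = spec$direction)
    if (spec$tool_end == "red") {
      return(dplyr::mutate(base, srt_ms = NA_real_, error_deg = NA_real_,
                           status = "red_excluded"))
    }
    ev <- events[events$trial_id == spec$trial_id, , drop = FALSE]
    sel <- select_response_saccade(ev, spec, p,
                                   any_blink = spec$trial_id %in% blink_trials)
    err <- if (sel$status == "valid") {
      compute_error(sel$event$landing_x, sel$event$landing_y,
                    spec$direction, p)
    } else NA_real_
    dplyr::mutate(base, srt_ms = sel$srt_ms, error_deg = err,
                  status = sel$status)
  })
  dplyr::bind_rows(rows)
}

#' Aggregate one subject's trials to condition-cell means
#'
#' Cell means are computed over valid trials only; red trials are excluded
#' before aggregation. The subject-average saccadic error in each cell is
#' rounded to the nearest multiple of `error_round_deg` (ties up), matching
#' the one-pixel resolution of the recording.
#'
#' @param results Trial results tibble from [trial_results()].
#' @param p [metrics_params()].
#' @param by Grouping columns defining the condition cells.
#' @return Tibble with one row per cell: `mean_srt_ms`, `mean_error_deg`
#'   (rounded), `n_valid`.
#' @export
aggregate_subject <- function(results, p = metrics_params(),
                              by = c("tool_end", "soa_ms")) {
  valid <- results %>%
    dplyr::filter(.data$status == "valid")
  valid %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      mean_srt_ms = mean(.data$srt_ms),
      mean_error_deg = round_to_multiple(mean(.data$error_deg),
                                         p$error_round_deg),
      n_valid = dplyr::n(), .groups = "drop")
}

#' Exclude subjects with poor data quality
#'
#' Operationalises the "loss of eye position" exclusion as a threshold on
#' the subject's overall fraction of missing samples.
#'
#' @param subjects Tibble with at least `subject_id` and `missing_frac`.
#' @param p [metrics_params()].
#' @return A list with `retained` (filtered tibble) and `log` (tibble of
#'   exclusions with reasons).
#' @export
apply_subject_exclusions <- function(subjects, p = metrics_params()) {
  thr <- p$subject_missing_exclusion_frac
  bad <- subjects$missing_frac > thr
  log <- tibble::tibble(
    subject_id = subjects$subject_id[bad],
    missing_frac = subjects$missing_frac[bad],
    reason = sprintf("missing-sample fraction %.3f exceeds %.3f",
                     subjects$missing_frac[bad], thr))
  list(retained = subjects[!bad, , drop = FALSE], log = log)
}

# ---- fast end-to-end per-subject path -------------------------------------

# Simulate and analyse one subject trial-by-trial without materialising the
# full session trace. Shares every core with the public stage functions.
process_subject_core <- function(schedule, subject_offset, k, lat, noise,
                                 fp, bp, dp, mp, target_ecc_deg, seed) {
  ba <- design_lowpass(fp)
  dt_s <- 1 / k$sample_rate
  withr::with_seed(seed, {
    n_missing <- 0L
    n_total <- 0L
    nt <- nrow(schedule)
    srt <- rep(NA_real_, nt)
    err <- rep(NA_real_, nt)
    true_srt <- rep(NA_real_, nt)
    status <- character(nt)
    for (i in seq_len(nt)) {
      cue_on <- schedule$cue_on_ms[i]
      trial_end <- schedule$trial_end_ms[i]
      cue_dir <- schedule$direction[i]
      mu <- trial_mu(lat, schedule$tool_end[i], schedule$soa_ms[i])
      tr <- sim_trial_core(cue_on, trial_end, schedule$image_off_ms[i],
                           cue_dir, mu, subject_offset, target_ecc_deg,
                           k, lat, noise)
      pp <- preprocess_core(tr$x, tr$y, tr$missing, fp, bp, ba)
      n_missing <- n_missing + sum(pp$missing)
      n_total <- n_total + length(pp$missing)
      true_srt[i] <- tr$truth$true_srt_ms
      if (schedule$tool_end[i] == "red") {
        status[i] <- "red_excluded"
        next
      }
      v <- velocity_core(pp$x, pp$y, dt_s)
      ev <- detect_events_core(v, dp$theta_all, dp$persistence)
      ne <- nrow(ev)
      ev_onset <- numeric(ne)
      ev_dir <- character(ne)
      ev_large <- logical(ne)
      ev_lx <- numeric(ne)
      ev_ly <- numeric(ne)
      for (r in seq_len(ne)) {
        on <- ev[r, 1]; off <- ev[r, 2]
        land <- landing_core(pp$x, pp$y, off, dp$landing_avg_samples)
        pk <- max(v[on:off], na.rm = TRUE)
        dx <- land$x - pp$x[on]
        ev_onset[r] <- tr$time_ms[on]
        ev_dir[r] <- if (is.na(dx)) NA_character_
        else if (dx < 0) "left" else "right"
        ev_large[r] <- pk >= dp$theta_big
        ev_lx[r] <- land$x
        ev_ly[r] <- land$y
      }
      any_blink <- any(pp$missing[tr$time_ms >= cue_on])
      sel <- select_response_core(ev_onset, ev_dir, ev_large, cue_on,
                                  trial_end, cue_dir, mp, any_blink)
      status[i] <- sel$status
      if (sel$status == "valid") {
        srt[i] <- sel$srt_ms
        err[i] <- compute_error(ev_lx[sel$idx], ev_ly[sel$idx], cue_dir, mp)
      }
    }
    results <- tibble::tibble(
      trial_id = schedule$trial_id, tool_end = schedule$tool_end,
      orientation = schedule$orientation, soa_ms = schedule$soa_ms,
      direction = schedule$direction, true_srt_ms = true_srt,
      srt_ms = srt, error_deg = err, status = status)
    list(results = results, missing_frac = n_missing / n_total)
  })
}

#' Simulate and analyse a full cohort end-to-end
#'
#' For each subject: build a schedule, simulate every trial's gaze trace,
#' preprocess (blink masking + zero-phase filtering), compute velocity,
#' detect saccades, select the response saccade and extract SRT and error —
#' without retaining the raw traces. Deterministic given `master_seed`.
#'
#' @param n_subjects Number of subjects.
#' @param design [design_params()].
#' @param k,lat,noise Generator parameter objects.
#' @param fp,bp,dp,mp Analysis parameter objects.
#' @param master_seed Integer master seed.
#' @return A list with `trials` (all subjects' trial results, including
#'   ground-truth SRT), `summaries` (subject x tool_end x soa cell means),
#'   and `subjects` (per-subject `missing_frac`).
#' @export
process_cohort <- function(n_subjects = 26, design = design_params(),
                           k = kinematics_params(), lat = latency_model(),
                           noise = noise_params(), fp = filter_params(),
                           bp = blink_params(), dp = detection_params(),
                           mp = metrics_params(), master_seed = 1L) {
  trials <- vector("list", n_subjects)
  summaries <- vector("list", n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cs <- child_seed(master_seed, i)
    offset <- withr::with_seed(cs, stats::rnorm(1, 0, lat$subject_sd))
    p <- design
    p$rng_seed <- cs + 1L
    schedule <- build_schedule(p)
    res <- process_subject_core(schedule, offset, k, lat, noise,
                                fp, bp, dp, mp, design$target_ecc_deg,
                                seed = cs + 2L)
    sid <- sprintf("s%02d", i)
    trials[[i]] <- dplyr::mutate(res$results, subject_id = sid,
                                 .before = 1)
    summaries[[i]] <- dplyr::mutate(
      aggregate_subject(res$results, mp), subject_id = sid, .before = 1)
    subjects[[i]] <- tibble::tibble(subject_id = sid,
                                    missing_frac = res$missing_frac,
                                    subject_offset = offset)
  }
  list(trials = dplyr::bind_rows(trials),
       summaries = dplyr::bind_rows(summaries),
       subjects = dplyr::bind_rows(subjects))
}
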