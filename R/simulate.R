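#' Saccade kinematics parameters (main sequence)
#'
#' Defaults are conventional oculomotor main-sequence constants: saccade
#' duration grows linearly with amplitude (`d0 + d1 * A` ms) and peak
#' velocity saturates exponentially (`vmax * (1 - exp(-A / a0))` deg/s).
#'
#' @param sample_rate Sampling rate in Hz.
#' @param d0,d1 Duration intercept (ms) and slope (ms/deg).
#' @param vmax,a0 Peak-velocity asymptote (deg/s) and amplitude constant (deg).
#' @param profile Velocity profile shape used when synthesising saccades.
#' @return A list of class `kinematics_params`.
#' @export
kinematics_params <- function(sample_rate = 300, d0 = 21, d1 = 2.2,
                              vmax = 500, a0 = 14,
                              profile = c("gaussian_velocity",
                                          "minimum_jerk")) {
  profile <- match.arg(profile)
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  if (d0 <= 0) stop_config("duration intercept d0 must be positive")
  structure(list(sample_rate = sample_rate, d0 = d0, d1 = d1,
                 vmax = vmax, a0 = a0, profile = profile),
            class = "kinematics_params")
}

#' Main-sequence duration and peak velocity
#'
#' @param amplitude Saccade amplitude in degrees (vectorised, `>= 0`).
#' @param k A [kinematics_params()] object.
#' @return Tibble with `duration_ms` and `peak_velocity` (deg/s).
#' @examples
#' main_sequence(12)  # 47.4 ms, ~288 deg/s with the defaults
#' @export
main_sequence <- function(amplitude, k = kinematics_params()) {
  stopifnot(all(amplitude >= 0))
  tibble::tibble(
    duration_ms = k$d0 + k$d1 * amplitude,
    peak_velocity = k$vmax * (1 - exp(-amplitude / k$a0))
  )
}

#' Saccadic latency model
#'
#' Ex-Gaussian trial-level latency with additive condition and SOA shifts and
#' a Gaussian between-subject offset. Defaults are calibrated to the
#' published per-condition subject means (head 393, handle 402, control
#' 402 ms), the SOA means (433/408/383/373 ms expressed as deviations from
#' their grand mean), and between-subject SEMs of ~10.6 ms over 26 subjects
#' (sd = 10.6 * sqrt(26) ~ 54 ms). Latencies are floored at `min_latency`.
#'
#' @param mu_by_condition Named vector of condition mean latencies, ms.
#' @param soa_effect Named vector (by SOA in ms) of additive latency shifts.
#' @param subject_sd Between-subject sd of the latency offset, ms.
#' @param trial_sd Gaussian trial-to-trial sd, ms.
#' @param exgauss_tau Exponential tail parameter, ms (mean-preserving:
#'   the exponential draw is recentered by `-tau`).
#' @param min_latency Hard floor on generated latencies, ms.
#' @return A list of class `latency_model`.
#' @export
latency_model <- function(mu_by_condition = c(head = 393, handle = 402,
                                              control = 402),
                          soa_effect = c(`100` = 33.75, `200` = 8.75,
                                         `400` = -16.25, `600` = -26.25),
                          subject_sd = 54, trial_sd = 40,
                          exgauss_tau = 30, min_latency = 80) {
  m <- list(mu_by_condition = mu_by_condition, soa_effect = soa_effect,
            subject_sd = subject_sd, trial_sd = trial_sd,
            exgauss_tau = exgauss_tau, min_latency = min_latency)
  if (!all(is.finite(unlist(m[-1]))) ||
      !all(is.finite(mu_by_condition)) || !all(is.finite(soa_effect))) {
    stop_config("all latency model components must be finite")
  }
  structure(m, class = "latency_model")
}

# One latency draw per trial; mean equals mu + subject_offset (before floor).
draw_latency <- function(lat, mu, subject_offset, n = length(mu)) {
  l <- mu + subject_offset +
    stats::rnorm(n, 0, lat$trial_sd) +
    (stats::rexp(n, 1 / lat$exgauss_tau) - lat$exgauss_tau)
  pmax(l, lat$min_latency)
}

#' Noise and artifact parameters for simulated gaze
#'
#' @param position_noise_rms Per-sample white position noise, degrees RMS.
#' @param blink_rate Blink events per minute.
#' @param blink_duration Min/max blink duration, ms (the minimum must span at
#'   least 10 samples so simulated blinks are detectable by the 10-sample
#'   signal-loss rule).
#' @param dropout_rate Per-sample probability of isolated signal loss.
#' @param overshoot_amp Post-saccadic ringing amplitude, degrees (exercises
#'   the 9-sample landing average).
#' @param landing_sd Saccade endpoint scatter about the target, degrees.
#' @param blink_spike_deg Vertical deflection on the samples flanking a blink
#'   (eyelid artifact), degrees; exercises the 20-sample padding rule.
#' @param sample_rate Sampling rate used to validate `blink_duration`.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(position_noise_rms = 0.1, blink_rate = 3,
                         blink_duration = c(100, 250), dropout_rate = 0.001,
                         overshoot_amp = 0.15, landing_sd = 0.5,
                         blink_spike_deg = 2, sample_rate = 300) {
  if (position_noise_rms < 0 || blink_rate < 0 || dropout_rate < 0) {
    stop_config("all noise rates must be non-negative")
  }
  if (blink_rate > 0 && blink_duration[1] < 10 * 1000 / sample_rate) {
    stop_config("blink_duration minimum must cover at least 10 samples")
  }
  structure(list(position_noise_rms = position_noise_rms,
                 blink_rate = blink_rate, blink_duration = blink_duration,
                 dropout_rate = dropout_rate, overshoot_amp = overshoot_amp,
                 landing_sd = landing_sd, blink_spike_deg = blink_spike_deg),
            class = "noise_params")
}

# Gaussian velocity profile helper. The profile peak equals the
# main-sequence peak velocity for the amplitude; sigma follows from the
# requirement that the profile integrate to the amplitude
# (A = Vp * sigma * sqrt(2*pi)). "Onset" is defined operationally as the
# time the profile first reaches `theta_ref` (the all-saccade detection
# threshold), so ground truth and the velocity-threshold detector agree.
# Returns times are in ms relative to the onset.
gauss_profile <- function(amplitude, k, theta_ref = 50, half_sigmas = 2.2) {
  vp <- k$vmax * (1 - exp(-amplitude / k$a0))
  sigma <- amplitude / (vp * sqrt(2 * pi)) * 1000  # ms
  # time from profile start (center - half_sigmas*sigma) to threshold crossing
  lead <- (half_sigmas - sqrt(2 * max(log(vp / theta_ref), 0))) * sigma
  list(vp = vp, sigma = sigma, lead_ms = lead,
       support_ms = 2 * half_sigmas * sigma, half_sigmas = half_sigmas)
}

# Add one saccade to position vectors x (in place semantics via return).
# onset_ms: threshold-crossing time; displacement (dx, dy) degrees.
add_saccade <- function(t_ms, x, y, onset_ms, dx, dy, k,
                        overshoot_amp = 0) {
  amp <- sqrt(dx^2 + dy^2)
  pr <- gauss_profile(amp, k)
  start <- onset_ms - pr$lead_ms
  center <- start + pr$support_ms / 2
  idx <- which(t_ms >= start & t_ms <= start + pr$support_ms)
  if (length(idx) < 2) return(list(x = x, y = y, end_ms = start))
  w <- exp(-((t_ms[idx] - center)^2) / (2 * pr$sigma^2))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  x[idx] <- x[idx] + dx * cdf
  y[idx] <- y[idx] + dy * cdf
  later <- t_ms > start + pr$support_ms
  x[later] <- x[later] + dx
  y[later] <- y[later] + dy
  end_ms <- start + pr$support_ms
  if (overshoot_amp > 0 && amp > 0) {
    # damped ringing along the saccade direction after landing
    ridx <- which(t_ms > end_ms & t_ms <= end_ms + 80)
    if (length(ridx) > 0) {
      tt <- (t_ms[ridx] - end_ms)
      ring <- overshoot_amp * exp(-tt / 20) * cos(2 * pi * 35 * tt / 1000)
      x[ridx] <- x[ridx] + ring * dx / amp
      y[ridx] <- y[ridx] + ring * dy / amp
    }
  }
  list(x = x, y = y, end_ms = end_ms)
}

# Core single-trial simulation on plain vectors. Caller controls the RNG.
sim_trial_core <- function(cue_on_ms, trial_end_ms, image_off_ms,
                           direction, mu_latency, subject_offset,
                           target_ecc_deg, k, lat, noise) {
  dt <- 1000 / k$sample_rate
  t_ms <- seq(0, trial_end_ms, by = dt)
  n <- length(t_ms)
  x <- numeric(n)
  y <- numeric(n)
  missing <- logical(n)
  truth <- list(true_saccade_onset_ms = NA_real_, true_srt_ms = NA_real_,
                true_landing_x = NA_real_, true_landing_y = NA_real_,
                omitted = FALSE, n_blinks = 0L)

  if (direction %in% c("left", "right")) {
    sgn <- if (direction == "right") 1 else -1
    latency <- draw_latency(lat, mu_latency, subject_offset, 1L)
    onset <- cue_on_ms + latency
    land_x <- sgn * target_ecc_deg + stats::rnorm(1, 0, noise$landing_sd)
    land_y <- stats::rnorm(1, 0, noise$landing_sd)
    pr <- gauss_profile(sqrt(land_x^2 + land_y^2), k)
    if (onset - pr$lead_ms + pr$support_ms > trial_end_ms - 2 * dt) {
      truth$omitted <- TRUE  # latency draw too late to complete: omission
    } else {
      s <- add_saccade(t_ms, x, y, onset, land_x, land_y, k,
                       overshoot_amp = noise$overshoot_amp)
      x <- s$x; y <- s$y
      truth$true_saccade_onset_ms <- onset
      truth$true_srt_ms <- latency
      truth$true_landing_x <- land_x
      truth$true_landing_y <- land_y
      # return saccade to center during the return phase
      ret_on <- max(image_off_ms, s$end_ms + dt) +
        pmax(stats::rnorm(1, 230, 40), 120)
      rpr <- gauss_profile(sqrt(land_x^2 + land_y^2), k)
      if (ret_on - rpr$lead_ms + rpr$support_ms < trial_end_ms - 2 * dt) {
        s2 <- add_saccade(t_ms, x, y, ret_on, -land_x, -land_y, k)
        x <- s2$x; y <- s2$y
      }
    }
  }

  if (noise$position_noise_rms > 0) {
    x <- x + stats::rnorm(n, 0, noise$position_noise_rms)
    y <- y + stats::rnorm(n, 0, noise$position_noise_rms)
  }

  blink_iv <- NULL
  if (noise$blink_rate > 0) {
    n_blink <- stats::rpois(1, noise$blink_rate * trial_end_ms / 60000)
    if (n_blink > 0) {
      for (b in seq_len(n_blink)) {
        dur <- stats::runif(1, noise$blink_duration[1],
                            noise$blink_duration[2])
        bstart <- stats::runif(1, 0, max(trial_end_ms - dur, 1))
        bi <- which(t_ms >= bstart & t_ms <= bstart + dur)
        if (length(bi) >= 10) {
          missing[bi] <- TRUE
          # eyelid deflection on flanking samples
          if (noise$blink_spike_deg > 0) {
            pre <- bi[1] - (1:2); post <- bi[length(bi)] + (1:2)
            pre <- pre[pre >= 1]; post <- post[post <= n]
            y[c(pre, post)] <- y[c(pre, post)] - noise$blink_spike_deg
          }
          blink_iv <- rbind(blink_iv, c(bi[1], bi[length(bi)]))
        }
      }
      truth$n_blinks <- if (is.null(blink_iv)) 0L else nrow(blink_iv)
    }
  }
  if (noise$dropout_rate > 0) {
    missing <- missing | stats::runif(n) < noise$dropout_rate
  }
  x[missing] <- NA_real_
  y[missing] <- NA_real_

  list(time_ms = t_ms, x = x, y = y, missing = missing, truth = truth,
       blink_intervals = blink_iv)
}

#' Simulate one trial's gaze trace with ground truth
#'
#' Generates a 300 Hz gaze trace for a single trial of the precueing design:
#' fixation at the screen center, one cued saccade of ~12 degrees whose
#' latency is drawn from the latency model (none on red trials), a return
#' saccade during the return phase, Gaussian position noise, optional blinks
#' and post-saccadic ringing. Ground-truth saccade onset is defined as the
#' time the noise-free velocity profile first reaches the 50 deg/s detection
#' threshold, so pipeline and ground truth share one onset convention.
#'
#' @param spec One schedule row (as from [build_schedule()]).
#' @param subject_offset Subject-level latency offset, ms.
#' @param k,lat,noise [kinematics_params()], [latency_model()],
#'   [noise_params()].
#' @param target_ecc_deg Target eccentricity, degrees.
#' @param seed Optional integer seed for this trial.
#' @return A list with `trace` (tibble: `trial_id`, `time_ms`, `x`, `y`,
#'   `missing`; degrees) and `truth` (one-row tibble of ground-truth fields,
#'   `true_srt_ms = true_saccade_onset_ms - cue_on_ms`).
#' @export
simulate_trial <- function(spec, subject_offset = 0,
                           k = kinematics_params(), lat = latency_model(),
                           noise = noise_params(), target_ecc_deg = 12,
                           seed = NULL) {
  run <- function() {
    mu <- trial_mu(lat, spec$tool_end, spec$soa_ms)
    sim_trial_core(spec$cue_on_ms, spec$trial_end_ms, spec$image_off_ms,
                   spec$direction, mu, subject_offset,
                   target_ecc_deg, k, lat, noise)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  trace <- tibble::tibble(trial_id = spec$trial_id, time_ms = res$time_ms,
                          x = res$x, y = res$y, missing = res$missing)
  truth <- tibble::as_tibble(res$truth[c(
    "true_saccade_onset_ms", "true_srt_ms", "true_landing_x",
    "true_landing_y", "omitted", "n_blinks")])
  truth <- dplyr::bind_cols(tibble::tibble(trial_id = spec$trial_id), truth)
  list(trace = trace, truth = truth)
}

# Mean latency for a design cell; red/none trials have no latency.
trial_mu <- function(lat, tool_end, soa_ms) {
  if (!(tool_end %in% names(lat$mu_by_condition))) return(NA_real_)
  soa_key <- as.character(soa_ms)
  shift <- if (soa_key %in% names(lat$soa_effect)) {
    lat$soa_effect[[soa_key]]
  } else 0
  lat$mu_by_condition[[tool_end]] + shift
}

#' Simulate a subject's full session
#'
#' @param schedule Schedule tibble from [build_schedule()].
#' @param subject_offset Subject latency offset, ms.
#' @inheritParams simulate_trial
#' @param seed Integer seed for the whole session.
#' @return List with `trace` (all trials row-bound, trial-relative
#'   `time_ms`) and `truth` (one row per trial).
#' @export
simulate_subject <- function(schedule, subject_offset = 0,
                             k = kinematics_params(), lat = latency_model(),
                             noise = noise_params(), target_ecc_deg = 12,
                             seed = 1L) {
  withr::with_seed(seed, {
    traces <- vector("list", nrow(schedule))
    truths <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      spec <- schedule[i, ]
      mu <- trial_mu(lat, spec$tool_end, spec$soa_ms)
      res <- sim_trial_core(spec$cue_on_ms, spec$trial_end_ms,
                            spec$image_off_ms, spec$direction, mu,
                            subject_offset, target_ecc_deg, k, lat, noise)
      traces[[i]] <- tibble::tibble(trial_id = spec$trial_id,
                                    time_ms = res$time_ms, x = res$x,
                                    y = res$y, missing = res$missing)
      truths[[i]] <- dplyr::bind_cols(
        tibble::tibble(trial_id = spec$trial_id),
        tibble::as_tibble(res$truth[c(
          "true_saccade_onset_ms", "true_srt_ms", "true_landing_x",
          "true_landing_y", "omitted", "n_blinks")]))
    }
    list(trace = dplyr::bind_rows(traces), truth = dplyr::bind_rows(truths))
  })
}

#' Simulate a cohort of subjects
#'
#' Each subject gets a deterministic child seed derived from the master seed
#' (so subjects can be regenerated independently and in any order), a fresh
#' randomized schedule, and a subject-level latency offset drawn with
#' `lat$subject_sd`.
#'
#' @param n_subjects Number of subjects.
#' @param design [design_params()] for every subject.
#' @inheritParams simulate_trial
#' @param master_seed Master integer seed.
#' @param dir Optional directory: gaze tables, schedules and ground-truth
#'   sidecar CSVs are written per subject.
#' @return A list (one element per subject) of
#'   `list(subject_id, schedule, trace, truth, subject_offset)`.
#' @export
simulate_cohort <- function(n_subjects = 26, design = design_params(),
                            k = kinematics_params(), lat = latency_model(),
                            noise = noise_params(), master_seed = 1L,
                            dir = NULL) {
  stopifnot(n_subjects >= 1)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cs <- child_seed(master_seed, i)
    offset <- withr::with_seed(cs, stats::rnorm(1, 0, lat$subject_sd))
    p <- design
    p$rng_seed <- cs + 1L
    schedule <- build_schedule(p)
    sim <- simulate_subject(schedule, offset, k, lat, noise,
                            design$target_ecc_deg, seed = cs + 2L)
    out[[i]] <- list(subject_id = sprintf("s%02d", i), schedule = schedule,
                     trace = sim$trace, truth = sim$truth,
                     subject_offset = offset)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      sid <- out[[i]]$subject_id
      write_gaze_table(sim$trace, file.path(dir, paste0("gaze_", sid, ".csv")))
      write_schedule(schedule, file.path(dir, paste0("schedule_", sid, ".csv")))
      readr::write_csv(sim$truth, file.path(dir, paste0("truth_", sid, ".csv")))
    }
  }
  out
}
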