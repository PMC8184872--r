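#' Saccade detection parameters
#'
#' Dual-threshold velocity detection: all saccades are detected at
#' `theta_all` (50 deg/s) and classified as large response saccades when
#' their peak velocity reaches `theta_big` (100 deg/s). A threshold crossing
#' must persist for `persistence` consecutive samples to open (or close) an
#' event. Landing points are averaged over `landing_avg_samples` samples
#' after the saccade offset to cancel filter-induced ringing.
#'
#' @param theta_all Detection threshold for all saccades, deg/s.
#' @param theta_big Classification threshold for large saccades, deg/s.
#' @param persistence Consecutive samples required for onset/offset.
#' @param landing_avg_samples Post-offset samples averaged for the landing
#'   point.
#' @param onset_at_big If `TRUE`, detection itself runs at `theta_big`
#'   (sensitivity-analysis mode); default detects at `theta_all` and
#'   classifies by peak velocity.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(theta_all = 50, theta_big = 100,
                             persistence = 3, landing_avg_samples = 9,
                             onset_at_big = FALSE) {
  if (!(theta_all > 0 && theta_all <= theta_big)) {
    stop_config("thresholds must satisfy 0 < theta_all <= theta_big")
  }
  if (persistence < 1) stop_config("persistence must be at least 1")
  structure(list(theta_all = theta_all, theta_big = theta_big,
                 persistence = as.integer(persistence),
                 landing_avg_samples = as.integer(landing_avg_samples),
                 onset_at_big = isTRUE(onset_at_big)),
            class = "detection_params")
}

# Core: combined-axis velocity by central differences (forward/backward at
# segment edges); NA where the sample or required neighbors are missing.
velocity_core <- function(x, y, dt_s) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n < 2) return(v)
  fx <- is.finite(x)
  xl <- c(NA, x[-n]); xr <- c(x[-1], NA)
  yl <- c(NA, y[-n]); yr <- c(y[-1], NA)
  fl <- c(FALSE, fx[-n]); fr <- c(fx[-1], FALSE)
  cen <- fx & fl & fr
  v[cen] <- sqrt((xr[cen] - xl[cen])^2 + (yr[cen] - yl[cen])^2) / (2 * dt_s)
  fwd <- fx & !fl & fr
  v[fwd] <- sqrt((xr[fwd] - x[fwd])^2 + (yr[fwd] - y[fwd])^2) / dt_s
  bwd <- fx & fl & !fr
  v[bwd] <- sqrt((x[bwd] - xl[bwd])^2 + (y[bwd] - yl[bwd])^2) / dt_s
  v
}

#' Combined-axis eye velocity
#'
#' Computes gaze speed from x and y jointly: central differences in the
#' interior of each finite segment, forward/backward differences at segment
#' edges, `NA` wherever the sample or a required neighbor is missing.
#'
#' @param trace Gaze trace tibble in degrees.
#' @param sample_rate Sampling rate, Hz; timestamps are checked against it.
#' @param jitter_tol Relative tolerance on the nominal sample step.
#' @return The trace with a `v` column (deg/s).
#' @export
gaze_velocity <- function(trace, sample_rate = 300, jitter_tol = 0.01) {
  dt_s <- 1 / sample_rate
  one <- function(df) {
    if (nrow(df) > 1) {
      dsteps <- diff(df$time_ms)
      if (any(abs(dsteps - 1000 * dt_s) > jitter_tol * 1000 * dt_s)) {
        abort("non-uniform timestamps beyond jitter tolerance")
      }
    }
    df$v <- velocity_core(df$x, df$y, dt_s)
    df
  }
  if ("trial_id" %in% names(trace)) {
    trace %>%
      dplyr::group_by(.data$trial_id) %>%
      dplyr::group_modify(~ one(.x)) %>%
      dplyr::ungroup() %>%
      dplyr::relocate("trial_id")
  } else {
    one(trace)
  }
}

# Core event segmentation. Returns an integer matrix (onset, offset).
# Onset: first sample of a run of >= persistence samples with v >= theta.
# Offset: last sample with v >= theta before a run of >= persistence
# below-threshold samples (or a missing sample / end of trace). Shorter
# below-threshold dips inside an event do not close it, which merges
# ringing-split saccades. Events never span missing samples.
detect_events_core <- function(v, theta, persistence) {
  n <- length(v)
  state <- ifelse(is.na(v), 0L, ifelse(v >= theta, 2L, 1L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- NULL
  in_event <- FALSE
  onset <- NA_integer_
  last_above <- NA_integer_
  for (i in seq_along(r$values)) {
    val <- r$values[i]; len <- r$lengths[i]
    if (!in_event) {
      if (val == 2L && len >= persistence) {
        in_event <- TRUE
        onset <- starts[i]
        last_above <- ends[i]
      }
    } else {
      if (val == 2L) {
        last_above <- ends[i]
      } else if (val == 0L || len >= persistence || i == length(r$values)) {
        events <- rbind(events, c(onset, last_above))
        in_event <- FALSE
        # a long-enough above-run would have to restart a new event; this
        # run is below/missing so nothing more to do here
      }
    }
  }
  if (in_event) events <- rbind(events, c(onset, last_above))
  if (is.null(events)) {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "offset")))
  } else {
    colnames(events) <- c("onset", "offset")
    events
  }
}

# Core landing point: mean of up to n_avg finite samples after offset_idx.
landing_core <- function(x, y, offset_idx, n_avg) {
  n <- length(x)
  idx <- seq(offset_idx + 1L, min(offset_idx + n_avg, n))
  idx <- idx[idx >= 1 & idx <= n]
  keep <- idx[is.finite(x[idx]) & is.finite(y[idx])]
  if (length(keep) == 0) {
    return(list(x = NA_real_, y = NA_real_, n_used = 0L))
  }
  list(x = mean(x[keep]), y = mean(y[keep]), n_used = length(keep))
}

#' Detect saccades from a velocity trace
#'
#' Dual-threshold, persistence-based segmentation: an event opens at the
#' first sample of a run of at least `persistence` samples at or above
#' `theta_all`, and closes before the next run of `persistence` samples
#' below it (or at a missing sample). The event is a large (response)
#' saccade when its peak velocity reaches `theta_big`. Landing point,
#' amplitude and direction are computed from the positions around the event.
#'
#' @param trace Gaze trace with a `v` column (from [gaze_velocity()]).
#' @param p [detection_params()].
#' @param sample_rate Sampling rate, Hz (for ms conversions).
#' @return Tibble of events: `trial_id` (if present), `onset_idx`,
#'   `offset_idx` (1-based within the trial segment), `onset_ms`,
#'   `offset_ms` (trial-relative), `peak_velocity`, `amplitude`,
#'   `direction`, `landing_x`, `landing_y`, `n_landing`, `is_large`.
#' @export
detect_saccades <- function(trace, p = detection_params(),
                            sample_rate = 300) {
  theta_det <- if (p$onset_at_big) p$theta_big else p$theta_all
  one <- function(df, id) {
    ev <- detect_events_core(df$v, theta_det, p$persistence)
    if (nrow(ev) == 0) return(NULL)
    rows <- lapply(seq_len(nrow(ev)), function(r) {
      on <- ev[r, 1]; off <- ev[r, 2]
      land <- landing_core(df$x, df$y, off, p$landing_avg_samples)
      pk <- max(df$v[on:off], na.rm = TRUE)
      dx <- land$x - df$x[on]
      dy <- land$y - df$y[on]
      tibble::tibble(
        trial_id = id, onset_idx = as.integer(on),
        offset_idx = as.integer(off),
        onset_ms = df$time_ms[on], offset_ms = df$time_ms[off],
        peak_velocity = pk,
        amplitude = sqrt(dx^2 + dy^2),
        direction = dplyr::case_when(is.na(dx) ~ NA_character_,
                                     dx < 0 ~ "left", TRUE ~ "right"),
        landing_x = land$x, landing_y = land$y,
        n_landing = land$n_used,
        is_large = pk >= p$theta_big)
    })
    dplyr::bind_rows(rows)
  }
  if ("trial_id" %in% names(trace)) {
    parts <- lapply(unique(trace$trial_id), function(id) {
      one(trace[trace$trial_id == id, ], id)
    })
    out <- dplyr::bind_rows(parts)
  } else {
    out <- one(trace, NA_integer_)
    if (!is.null(out)) out$trial_id <- NULL
  }
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      trial_id = integer(), onset_idx = integer(), offset_idx = integer(),
      onset_ms = numeric(), offset_ms = numeric(), peak_velocity = numeric(),
      amplitude = numeric(), direction = character(), landing_x = numeric(),
      landing_y = numeric(), n_landing = integer(), is_large = logical())
    if (!("trial_id" %in% names(trace))) out$trial_id <- NULL
  }
  out
}

#' Post-saccadic landing point
#'
#' Mean gaze position over up to `landing_avg_samples` finite samples after
#' the saccade offset, compensating ringing-related overshoot; the number of
#' samples actually used is reported.
#'
#' @param trace Gaze trace tibble (one trial segment).
#' @param offset_idx Saccade offset sample index (1-based).
#' @param p [detection_params()].
#' @return One-row tibble: `landing_x`, `landing_y`, `n_used`.
#' @export
landing_point <- function(trace, offset_idx, p = detection_params()) {
  l <- landing_core(trace$x, trace$y, offset_idx, p$landing_avg_samples)
  tibble::tibble(landing_x = l$x, landing_y = l$y, n_used = l$n_used)
}
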