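#' Low-pass filter parameters
#'
#' The position filter is a Chebyshev type II low-pass whose stopband starts
#' at `stopband_edge * pi` rad/sample with `stopband_attenuation_db` of
#' attenuation, applied forward and backward (zero phase, no group delay) so
#' saccade timing is not shifted. Chebyshev II places its specification
#' exactly at these two printed numbers and has a maximally flat passband.
#'
#' @param stopband_edge Stopband edge as a fraction of the Nyquist frequency
#'   (i.e. in units of pi rad/sample); default 0.3.
#' @param stopband_attenuation_db Minimum stopband attenuation in dB.
#' @param order Filter order (of the single-pass prototype).
#' @param zero_phase Apply forward-backward (zero-phase) filtering.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(stopband_edge = 0.3, stopband_attenuation_db = 60,
                          order = 8, zero_phase = TRUE) {
  if (stopband_edge <= 0 || stopband_edge >= 1) {
    stop_config("stopband_edge must lie strictly between 0 and 1 (x pi rad/sample)")
  }
  if (stopband_attenuation_db <= 0) {
    stop_config("stopband attenuation must be positive")
  }
  structure(list(stopband_edge = stopband_edge,
                 stopband_attenuation_db = stopband_attenuation_db,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_params")
}

design_lowpass <- function(p = filter_params()) {
  signal::cheby2(p$order, p$stopband_attenuation_db, p$stopband_edge)
}

# Zero-phase filtering with odd-reflection padding at both ends (controls
# the edge transients of the forward and backward passes).
filtfilt_refl <- function(ba, x) {
  L <- length(x)
  np <- min(L - 1L, 8L * (length(ba$a) - 1L))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[L] - x[(L - 1):(L - np)])
  # endpoint detrend so the zero-state transients of both passes act on a
  # signal that starts and ends at zero (the filter has unit DC gain)
  n <- length(xp)
  line <- xp[1] + (xp[n] - xp[1]) * (seq_len(n) - 1) / (n - 1)
  y <- signal::filter(ba, xp - line)
  y <- rev(signal::filter(ba, rev(y)))
  (y + line)[(np + 1):(np + L)]
}

# Filter one numeric vector segment-wise across NA gaps.
filter_segments <- function(x, ba, min_len) {
  runs <- true_runs(is.finite(x))
  if (nrow(runs) == 0) return(x)
  for (r in seq_len(nrow(runs))) {
    i0 <- runs[r, 1]; i1 <- runs[r, 2]
    if (i1 - i0 + 1L >= min_len) {
      x[i0:i1] <- filtfilt_refl(ba, x[i0:i1])
    }
  }
  x
}

# Core: filter x and y per contiguous finite segment; short segments are
# left unfiltered.
lowpass_core <- function(x, y, p, ba = design_lowpass(p)) {
  min_len <- 3L * (p$order + 1L)
  list(x = filter_segments(x, ba, min_len),
       y = filter_segments(y, ba, min_len))
}

#' Zero-phase low-pass filtering of gaze position
#'
#' Overwrites the `x` and `y` columns with filtered values. Filtering is
#' applied independently to every contiguous run of finite samples (within
#' each trial when a `trial_id` column is present); nothing is interpolated
#' across missing gaps, and segments too short to filter (fewer than
#' `3 * (order + 1)` samples) are left untouched.
#'
#' @param trace Gaze trace tibble (`time_ms`, `x`, `y`, `missing`, optional
#'   `trial_id`).
#' @param p [filter_params()].
#' @return The trace with filtered positions.
#' @export
lowpass_zero_phase <- function(trace, p = filter_params()) {
  ba <- design_lowpass(p)
  apply_grp <- function(df) {
    f <- lowpass_core(df$x, df$y, p, ba)
    df$x <- f$x
    df$y <- f$y
    df
  }
  if ("trial_id" %in% names(trace)) {
    trace %>%
      dplyr::group_by(.data$trial_id) %>%
      dplyr::group_modify(~ apply_grp(.x)) %>%
      dplyr::ungroup() %>%
      dplyr::relocate("trial_id")
  } else {
    apply_grp(trace)
  }
}

#' Blink-masking parameters
#'
#' A blink is a loss of eye position lasting at least `min_gap_samples`
#' continuous samples; `pad_before`/`pad_after` extra samples are removed on
#' each side to suppress the velocity distortions of eyelid closure.
#'
#' @param min_gap_samples Minimum run of lost samples that counts as a blink.
#' @param pad_before,pad_after Samples removed before/after each blink.
#' @return A list of class `blink_params`.
#' @export
blink_params <- function(min_gap_samples = 10, pad_before = 20,
                         pad_after = 20) {
  if (min_gap_samples < 0 || pad_before < 0 || pad_after < 0) {
    stop_config("blink parameters must be non-negative")
  }
  structure(list(min_gap_samples = as.integer(min_gap_samples),
                 pad_before = as.integer(pad_before),
                 pad_after = as.integer(pad_after)),
            class = "blink_params")
}

# Core: maximal runs of missing with length >= min_gap (matrix start,end).
detect_blinks_core <- function(missing, min_gap) {
  runs <- true_runs(missing)
  runs[runs[, 2] - runs[, 1] + 1L >= min_gap, , drop = FALSE]
}

# Core: extend intervals by padding (clipped) and set missing.
mask_blinks_core <- function(missing, intervals, pad_before, pad_after) {
  n <- length(missing)
  if (!is.null(intervals) && nrow(intervals) > 0) {
    for (r in seq_len(nrow(intervals))) {
      i0 <- max(1L, intervals[r, 1] - pad_before)
      i1 <- min(n, intervals[r, 2] + pad_after)
      missing[i0:i1] <- TRUE
    }
  }
  missing
}

#' Detect blinks from signal loss
#'
#' @param trace Gaze trace tibble with a `missing` column.
#' @param p [blink_params()].
#' @return Tibble of blink intervals (`trial_id` if present, `start_idx`,
#'   `end_idx`, `n_samples`); sample indices are 1-based within each trial
#'   segment. Gaps shorter than `min_gap_samples` are not blinks.
#' @export
detect_blinks <- function(trace, p = blink_params()) {
  one <- function(missing, id) {
    m <- detect_blinks_core(missing, p$min_gap_samples)
    tibble::tibble(trial_id = id,
                   start_idx = as.integer(m[, 1]),
                   end_idx = as.integer(m[, 2]),
                   n_samples = as.integer(m[, 2] - m[, 1] + 1L))
  }
  if ("trial_id" %in% names(trace)) {
    ids <- unique(trace$trial_id)
    dplyr::bind_rows(lapply(ids, function(id) {
      one(trace$missing[trace$trial_id == id], id)
    }))
  } else {
    out <- one(trace$missing, NA_integer_)
    out$trial_id <- NULL
    out
  }
}

#' Mask blinks with padding
#'
#' Extends each blink interval by the padding in `p`, clipped at the trace
#' (or trial-segment) edges, and sets those samples to missing. Finite
#' samples are never created; the finite-sample count never increases.
#'
#' @param trace Gaze trace tibble.
#' @param intervals Blink intervals as from [detect_blinks()]; detected from
#'   the trace when `NULL`.
#' @param p [blink_params()].
#' @return The trace with masked samples set to missing (`NA` positions).
#' @export
mask_blinks <- function(trace, intervals = NULL, p = blink_params()) {
  if (is.null(intervals)) intervals <- detect_blinks(trace, p)
  apply_one <- function(df, iv) {
    m <- mask_blinks_core(df$missing,
                          as.matrix(iv[, c("start_idx", "end_idx")]),
                          p$pad_before, p$pad_after)
    df$missing <- m
    df$x[m] <- NA_real_
    df$y[m] <- NA_real_
    df
  }
  if ("trial_id" %in% names(trace) && "trial_id" %in% names(intervals)) {
    parts <- lapply(unique(trace$trial_id), function(id) {
      apply_one(trace[trace$trial_id == id, ],
                intervals[!is.na(intervals$trial_id) &
                            intervals$trial_id == id, ])
    })
    dplyr::bind_rows(parts)
  } else {
    apply_one(trace, intervals)
  }
}

# Core: full preprocessing of one trial's vectors (mask, then filter).
preprocess_core <- function(x, y, missing, fp, bp, ba) {
  iv <- detect_blinks_core(missing, bp$min_gap_samples)
  missing <- mask_blinks_core(missing, iv, bp$pad_before, bp$pad_after)
  x[missing] <- NA_real_
  y[missing] <- NA_real_
  f <- lowpass_core(x, y, fp, ba)
  list(x = f$x, y = f$y, missing = missing)
}

#' Preprocess a gaze trace (blink masking, then filtering)
#'
#' Blink detection and padded masking are applied to the raw validity flags
#' first; the zero-phase low-pass filter is then run over each remaining
#' contiguous finite segment. Masking must precede filtering because the
#' filter cannot cross missing values and interpolation would fabricate
#' data.
#'
#' @param trace Gaze trace tibble.
#' @param fp [filter_params()].
#' @param bp [blink_params()].
#' @return Preprocessed trace.
#' @export
preprocess_trace <- function(trace, fp = filter_params(),
                             bp = blink_params()) {
  trace <- mask_blinks(trace, NULL, bp)
  lowpass_zero_phase(trace, fp)
}
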