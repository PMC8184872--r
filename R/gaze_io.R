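#' Read a raw gaze sample table
#'
#' Parses a delimited export of raw gaze samples (timestamp, x/y position,
#' validity, in the style of a Tobii SDK dump) into a tidy gaze trace.
#' Samples flagged invalid, or with non-finite positions, become missing;
#' timestamps are normalised to ms from recording start and checked for
#' monotonicity and sampling jitter.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named character vector mapping the required roles
#'   (`timestamp`, `x`, `y`, `validity`, optionally `trial_id`) to the file's
#'   column names. Validity follows the convention 0 = valid.
#' @param geometry Optional [screen_geometry()]; when supplied and
#'   `unit = "px"`, positions are converted to degrees.
#' @param unit Unit of the position columns in the file.
#' @param sample_rate Nominal sampling rate in Hz, used for the jitter check.
#' @param jitter_tol Relative tolerance on the nominal sample step before a
#'   jitter warning is raised.
#' @return A tibble with `time_ms`, `x`, `y`, `missing` (and `trial_id` if
#'   present), positions in degrees when a geometry was given.
#' @export
read_gaze_table <- function(path,
                            column_map = c(timestamp = "timestamp",
                                           x = "x", y = "y",
                                           validity = "validity"),
                            geometry = NULL,
                            unit = c("deg", "px"),
                            sample_rate = 300,
                            jitter_tol = 0.01) {
  unit <- match.arg(unit)
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- intersect(c("timestamp", "x", "y", "validity", "trial_id"),
                    names(column_map))
  miss <- setdiff(unname(column_map[need]), names(raw))
  if (length(miss) > 0) {
    abort(sprintf("mapped columns absent from %s: %s", path,
                  paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(raw), unname(column_map))
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown columns: %s", paste(extra, collapse = ", ")))
  }

  out <- tibble::tibble(
    time_ms = as.numeric(raw[[column_map[["timestamp"]]]]),
    x = as.numeric(raw[[column_map[["x"]]]]),
    y = as.numeric(raw[[column_map[["y"]]]]),
    missing = raw[[column_map[["validity"]]]] != 0
  )
  if ("trial_id" %in% names(column_map) &&
      column_map[["trial_id"]] %in% names(raw)) {
    out$trial_id <- raw[[column_map[["trial_id"]]]]
    out <- out[, c("trial_id", "time_ms", "x", "y", "missing")]
  }

  out$missing <- out$missing | !is.finite(out$x) | !is.finite(out$y)
  out$x[out$missing] <- NA_real_
  out$y[out$missing] <- NA_real_

  grp <- if ("trial_id" %in% names(out)) out$trial_id else
    rep(1L, nrow(out))
  for (g in unique(grp)) {
    tm <- out$time_ms[grp == g]
    if (length(tm) > 1) {
      dt <- diff(tm)
      if (any(dt <= 0)) abort("nonmonotonic timestamps in gaze table")
      step <- 1000 / sample_rate
      if (any(abs(dt - step) > jitter_tol * step)) {
        warn(sprintf(
          "sampling jitter beyond %g%% of the nominal %0.3f ms step",
          100 * jitter_tol, step))
      }
    }
  }
  out$time_ms <- out$time_ms - min(out$time_ms)

  if (unit == "px" && !is.null(geometry)) {
    d <- px_to_deg(out$x, out$y, geometry)
    out$x <- d$x_deg
    out$y <- d$y_deg
    out$x[out$missing] <- NA_real_
    out$y[out$missing] <- NA_real_
  }
  out
}

#' Write a gaze trace as a raw sample table
#'
#' Inverse of [read_gaze_table()]: writes `timestamp`, `x`, `y`, `validity`
#' (0 = valid, 4 = lost) columns, preserving missingness exactly.
#'
#' @param trace Gaze trace tibble.
#' @param path Output CSV path.
#' @export
write_gaze_table <- function(trace, path) {
  out <- tibble::tibble(
    timestamp = trace$time_ms,
    x = trace$x, y = trace$y,
    validity = ifelse(trace$missing, 4L, 0L)
  )
  if ("trial_id" %in% names(trace)) {
    out <- dplyr::bind_cols(tibble::tibble(trial_id = trace$trial_id), out)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
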