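# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Round to the nearest multiple of `q`, ties away from zero handled as ties up
# (matching subject-average error rounding to one pixel's worth of degrees).
round_to_multiple <- function(x, q, eps = 1e-9) {
  floor(x / q + 0.5 + eps) * q
}

# Maximal runs of TRUE in a logical vector; NA counts as FALSE.
# Returns a two-column matrix (start, end), 1-based inclusive.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Deterministic per-subject child seed below 2^31.
child_seed <- function(master_seed, i) {
  (as.integer(master_seed) %% 1000000L) * 1000L + (as.integer(i) %% 1000L)
}

stop_config <- function(msg) abort(msg, class = "gazeprime_config_error")
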