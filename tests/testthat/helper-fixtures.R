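# Shared fixtures and independent oracles, built in code at test time.

# A minimal gaze trace tibble at 300 Hz from x/y vectors.
make_trace <- function(x, y = rep(0, length(x)), missing = NULL,
                       sample_rate = 300, trial_id = NULL) {
  n <- length(x)
  if (is.null(missing)) missing <- !is.finite(x) | !is.finite(y)
  tr <- tibble::tibble(
    time_ms = (seq_len(n) - 1) * 1000 / sample_rate,
    x = ifelse(missing, NA_real_, x),
    y = ifelse(missing, NA_real_, y),
    missing = missing)
  if (!is.null(trial_id)) {
    tr <- dplyr::bind_cols(tibble::tibble(trial_id = trial_id), tr)
  }
  tr
}

# A trace whose velocity is (approximately) a given profile: integrate
# v (deg/s) at the sample rate along x.
trace_from_velocity <- function(v, sample_rate = 300) {
  x <- cumsum(v) / sample_rate
  make_trace(x)
}

# A trace carrying an explicit velocity column (for direct detector tests).
make_v_trace <- function(v, sample_rate = 300) {
  tr <- trace_from_velocity(ifelse(is.na(v), 0, v), sample_rate)
  tr$x[is.na(v)] <- NA_real_
  tr$missing <- is.na(v)
  tr$v <- v
  tr
}

# Independent brute-force event oracle: a literal per-sample state machine,
# structurally unlike the rle-based implementation. Returns (onset, offset)
# matrix with the dual-run semantics: an event opens at the first sample of
# a run of >= persistence above-threshold samples and closes at the last
# above-threshold sample before a run of >= persistence below-threshold
# samples, a missing sample, or the end of the trace.
oracle_detect <- function(v, theta, persistence) {
  n <- length(v)
  events <- matrix(integer(0), ncol = 2)
  i <- 1L
  while (i <= n) {
    # find a run of >= persistence consecutive above-threshold samples
    run_ok <- function(j) {
      if (j + persistence - 1 > n) return(FALSE)
      for (t in j:(j + persistence - 1)) {
        if (is.na(v[t]) || v[t] < theta) return(FALSE)
      }
      TRUE
    }
    while (i <= n && !run_ok(i)) i <- i + 1
    if (i > n) break
    onset <- i
    last_above <- i
    j <- i
    below_run <- 0
    while (j <= n) {
      if (is.na(v[j])) break
      if (v[j] >= theta) {
        last_above <- j
        below_run <- 0
      } else {
        below_run <- below_run + 1
        if (below_run >= persistence) break
      }
      j <- j + 1
    }
    events <- rbind(events, c(onset, last_above))
    i <- j + 1
  }
  colnames(events) <- c("onset", "offset")
  storage.mode(events) <- "integer"
  events
}

# Brute-force one-way repeated-measures ANOVA by explicit summation
# (textbook formulas, independent of the array decomposition).
brute_rm_anova_1w <- function(mat) {  # subjects x conditions
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  cond_means <- colMeans(mat)
  subj_means <- rowMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       ss_total = ss_total, df1 = df1, df2 = df2,
       eta_g2 = ss_cond / (ss_cond + ss_subj + ss_err))
}

# Subjects-x-conditions matrix whose sample covariance is exactly spherical
# (orthonormal centered columns), so the GG epsilon equals 1 exactly.
spherical_matrix <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n, k)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    qr.Q(qr(Xc))[, seq_len(k)]
  })
}

# Long tibble from a subjects x conditions matrix.
long_from_matrix <- function(mat, cond_name = "cond") {
  tibble::tibble(
    subject_id = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    cond = factor(rep(seq_len(ncol(mat)), each = nrow(mat))),
    dv = as.vector(mat)) |>
    dplyr::rename(!!cond_name := "cond")
}

# Noise-free generator settings shared by recovery tests.
noiseless_latency <- function(mu = 400) {
  latency_model(
    mu_by_condition = c(head = mu, handle = mu, control = mu),
    soa_effect = c(`100` = 0, `200` = 0, `400` = 0, `600` = 0),
    subject_sd = 0, trial_sd = 0, exgauss_tau = 1e-9)
}

noiseless_noise <- function() {
  noise_params(position_noise_rms = 0, blink_rate = 0, dropout_rate = 0,
               overshoot_amp = 0, landing_sd = 0, blink_spike_deg = 0)
}

# Small one-block design (counts divisible by soa x direction cells).
small_design <- function(rng_seed = 1L, ...) {
  design_params(n_blocks = 1, trials_per_block = 84, n_head = 32,
                n_handle = 32, n_control = 16, n_red = 4,
                rng_seed = rng_seed, ...)
}
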