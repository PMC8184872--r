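test_that("combined-axis velocity follows the kinematics of the trace", {
  n <- 60
  drift <- make_trace(0.1 * seq_len(n))
  v <- gaze_velocity(drift)$v
  expect_equal(v[5:55], rep(30, 51))  # 0.1 deg/sample at 300 Hz

  diag2 <- make_trace(0.1 * seq_len(n), 0.1 * seq_len(n))
  expect_equal(gaze_velocity(diag2)$v[10], 30 * sqrt(2), tolerance = 1e-9)

  still <- make_trace(rep(4, n), rep(-2, n))
  expect_equal(gaze_velocity(still)$v, rep(0, n))

  gap <- make_trace(c(0.1 * 1:20, NA, 0.1 * 22:40))
  vg <- gaze_velocity(gap)$v
  expect_true(is.na(vg[21]))
  # neighbors of the gap fall back to one-sided differences
  expect_equal(vg[20], 30, tolerance = 1e-9)
  expect_equal(vg[22], 30, tolerance = 1e-9)
})

test_that("non-uniform sampling is rejected", {
  tr <- make_trace(1:20)
  tr$time_ms[10] <- tr$time_ms[10] + 2
  expect_error(gaze_velocity(tr), "non-uniform")
})

test_that("dual thresholds with 3-sample persistence segment rectangular pulses", {
  pulse <- function(amp, len, pad = 15) c(rep(0, pad), rep(amp, len),
                                          rep(0, pad))
  ev <- detect_saccades(make_v_trace(pulse(120, 10)))
  expect_equal(nrow(ev), 1)
  expect_true(ev$is_large)
  expect_equal(ev$onset_idx, 16L)  # first sample of the above-threshold run
  expect_equal(ev$offset_idx, 25L)

  # 2 samples above threshold: no event (persistence = 3)
  ev2 <- detect_saccades(make_v_trace(c(rep(0, 10), 120, 120, rep(0, 10))))
  expect_equal(nrow(ev2), 0)

  # 60 deg/s pulse: detected but not large (50 <= peak < 100)
  ev3 <- detect_saccades(make_v_trace(c(rep(0, 10), rep(60, 10),
                                        rep(0, 10))))
  expect_equal(nrow(ev3), 1)
  expect_false(ev3$is_large)
})

test_that("event segmentation equals the brute-force oracle on random traces", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      n <- sample(20:60, 1)
      v <- sample(c(0, 30, 60, 120, NA), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.2, 0.1))
      got <- gazeprime:::detect_events_core(v, 50, 3)
      want <- oracle_detect(v, 50, 3)
      expect_identical(unname(got[, , drop = TRUE]),
                       unname(want[, , drop = TRUE]),
                       info = paste("trace", i))
    }
  })
})

test_that("raising the detection threshold never increases the event count", {
  withr::with_seed(11, {
    for (i in 1:30) {
      v <- sample(c(0, 40, 80, 150), 50, replace = TRUE)
      n_lo <- nrow(gazeprime:::detect_events_core(v, 50, 3))
      n_hi <- nrow(gazeprime:::detect_events_core(v, 90, 3))
      expect_lte(n_hi, n_lo)
    }
  })
})

test_that("detector output is invariant to missing padding outside events", {
  v <- c(rep(0, 10), rep(120, 8), rep(0, 10))
  base <- gazeprime:::detect_events_core(v, 50, 3)
  padded <- gazeprime:::detect_events_core(c(rep(NA, 7), v, rep(NA, 7)),
                                           50, 3)
  expect_equal(unname(padded - 7L), unname(base))
})

test_that("landing point averages up to nine post-offset samples", {
  x <- c(rep(0, 10), rep(12, 20))
  tr <- make_trace(x)
  lp <- landing_point(tr, offset_idx = 12)
  expect_equal(lp$landing_x, 12)
  expect_equal(lp$n_used, 9)

  # symmetric decaying ringing around 12: average is closer than the
  # single post-offset sample
  ring <- 12 + 0.6 * exp(-(1:9) / 3) * cos(pi * (1:9))
  tr2 <- make_trace(c(rep(0, 10), 11.5, ring, rep(12, 5)))
  lp2 <- landing_point(tr2, offset_idx = 11)
  expect_lt(abs(lp2$landing_x - 12), abs(tr2$x[12] - 12))

  # truncated window: only 4 finite samples remain
  tr3 <- make_trace(c(rep(0, 10), rep(12, 4), rep(NA, 10)))
  lp3 <- landing_point(tr3, offset_idx = 10)
  expect_equal(lp3$n_used, 4)
  expect_equal(lp3$landing_x, 12)
})

test_that("noise-free synthetic saccades are recovered at sample precision", {
  s <- build_schedule(small_design())
  specs <- s[s$direction != "none", ][1:8, ]
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    tr <- simulate_trial(spec, 0, lat = noiseless_latency(380),
                         noise = noiseless_noise(), seed = 100 + i)
    ev <- detect_saccades(gaze_velocity(tr$trace))
    big <- ev[ev$is_large & ev$onset_ms > spec$cue_on_ms, ]
    expect_gte(nrow(big), 1)
    expect_lt(abs(big$onset_ms[1] - tr$truth$true_saccade_onset_ms),
              1000 / 300 + 1e-9)
    expect_lt(abs(big$landing_x[1] - tr$truth$true_landing_x), 0.05)
    expect_lt(abs(big$landing_y[1] - tr$truth$true_landing_y), 0.05)
  }
})
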