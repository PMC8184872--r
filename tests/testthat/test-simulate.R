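test_that("main sequence obeys the duration and peak-velocity laws", {
  ms0 <- main_sequence(0)
  expect_equal(ms0$duration_ms, 21)
  expect_equal(ms0$peak_velocity, 0)
  expect_equal(main_sequence(12)$duration_ms, 47.4)  # 21 + 2.2 * 12
  expect_gt(main_sequence(12)$peak_velocity, main_sequence(6)$peak_velocity)
  amps <- seq(0.5, 25, by = 0.5)
  pv <- main_sequence(amps)$peak_velocity
  expect_true(all(diff(pv) > 0))
  expect_true(all(main_sequence(amps)$duration_ms > 0))
})

test_that("noise-free fixed-latency trial has its onset at cue + latency", {
  p <- design_params()
  s <- build_schedule(p)
  spec <- s[which(s$direction == "right" & s$soa_ms == 400)[1], ]
  tr <- simulate_trial(spec, 0, lat = noiseless_latency(400),
                       noise = noiseless_noise(), seed = 1)
  expect_equal(tr$truth$true_saccade_onset_ms, 1300)  # 500 + 400 + 400
  expect_equal(tr$truth$true_srt_ms, 400)
  expect_equal(tr$truth$true_srt_ms,
               tr$truth$true_saccade_onset_ms - spec$cue_on_ms)
})

test_that("noise-free saccades satisfy the amplitude and peak-velocity contracts", {
  s <- build_schedule(small_design())
  specs <- s[s$direction != "none", ][1:6, ]
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    tr <- simulate_trial(spec, 0, lat = noiseless_latency(350),
                         noise = noiseless_noise(), seed = i)
    sgn <- if (spec$direction == "right") 1 else -1
    # displacement across the saccade equals the requested amplitude
    plateau <- tr$trace$x[tr$trace$time_ms > tr$truth$true_saccade_onset_ms + 80 &
                            tr$trace$time_ms < spec$image_off_ms]
    expect_lt(abs(mean(plateau) - sgn * 12), 0.05)
    # numerically differentiated peak within 5% of the main-sequence peak
    win <- tr$trace$time_ms > spec$cue_on_ms & tr$trace$time_ms < spec$image_off_ms
    v <- gaze_velocity(tr$trace)$v[win]
    expect_lt(abs(max(v, na.rm = TRUE) - main_sequence(12)$peak_velocity) /
                main_sequence(12)$peak_velocity, 0.05)
  }
})

test_that("red trials produce no saccade and no ground-truth SRT", {
  s <- build_schedule(design_params())
  spec <- s[s$tool_end == "red", ][1, ]
  tr <- simulate_trial(spec, 0, lat = latency_model(),
                       noise = noiseless_noise(), seed = 3)
  expect_true(is.na(tr$truth$true_srt_ms))
  v <- gaze_velocity(tr$trace)$v
  expect_true(all(v[!is.na(v)] < 100))
})

test_that("injected blinks always span at least 10 samples", {
  s <- build_schedule(small_design())
  spec <- s[s$direction != "none", ][1, ]
  nz <- noise_params(position_noise_rms = 0, blink_rate = 60,
                     blink_duration = c(100, 250), dropout_rate = 0)
  found <- 0
  for (seed in 1:10) {
    tr <- simulate_trial(spec, 0, noise = nz, seed = seed)
    iv <- detect_blinks(tr$trace)
    if (nrow(iv) > 0) {
      found <- found + nrow(iv)
      expect_true(all(iv$n_samples >= 10))
    }
  }
  expect_gt(found, 0)
})

test_that("simulation is deterministic given the seed", {
  s <- build_schedule(small_design())
  a <- simulate_subject(s[1:10, ], 5, seed = 99)
  b <- simulate_subject(s[1:10, ], 5, seed = 99)
  expect_identical(a, b)
  c1 <- simulate_cohort(2, small_design(), master_seed = 7)
  c2 <- simulate_cohort(2, small_design(), master_seed = 7)
  expect_identical(c1, c2)
})

test_that("cohorts have the right shape and zero-variance subjects share SRTs", {
  coh <- simulate_cohort(2, small_design(), master_seed = 1)
  expect_length(coh, 2)
  expect_equal(nrow(coh[[1]]$truth), 84)
  expect_equal(dplyr::n_distinct(coh[[1]]$trace$trial_id), 84)

  lat0 <- noiseless_latency(400)
  coh0 <- simulate_cohort(2, small_design(), lat = lat0,
                          noise = noiseless_noise(), master_seed = 1)
  srt1 <- sort(coh0[[1]]$truth$true_srt_ms)
  srt2 <- sort(coh0[[2]]$truth$true_srt_ms)
  expect_equal(srt1, srt2)
})

test_that("cohort files on disk round-trip and carry one gaze table per subject", {
  dir <- withr::local_tempdir()
  simulate_cohort(2, small_design(), master_seed = 2, dir = dir)
  expect_length(list.files(dir, pattern = "^gaze_"), 2)
  expect_length(list.files(dir, pattern = "^truth_"), 2)
  tr <- read_gaze_table(
    file.path(dir, "gaze_s01.csv"),
    column_map = c(timestamp = "timestamp", x = "x", y = "y",
                   validity = "validity", trial_id = "trial_id"))
  expect_equal(dplyr::n_distinct(tr$trial_id), 84)
})

test_that("late latency draws become ground-truth omissions, not errors", {
  s <- build_schedule(small_design())
  spec <- s[s$direction != "none" & s$soa_ms == 600, ][1, ]
  lat_late <- latency_model(
    mu_by_condition = c(head = 2000, handle = 2000, control = 2000),
    soa_effect = c(`100` = 0, `200` = 0, `400` = 0, `600` = 0),
    subject_sd = 0, trial_sd = 0, exgauss_tau = 1e-9)
  tr <- simulate_trial(spec, 0, lat = lat_late, noise = noiseless_noise(),
                       seed = 1)
  expect_true(tr$truth$omitted)
  expect_true(is.na(tr$truth$true_srt_ms))
})
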