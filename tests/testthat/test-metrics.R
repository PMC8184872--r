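mk_events <- function(onset_ms, is_large = TRUE, direction = "right",
                      landing_x = 12, landing_y = 0) {
  tibble::tibble(trial_id = 1L, onset_idx = 1L, offset_idx = 2L,
                 onset_ms = onset_ms, offset_ms = onset_ms + 50,
                 peak_velocity = ifelse(is_large, 300, 70),
                 amplitude = 12, direction = direction,
                 landing_x = landing_x, landing_y = landing_y,
                 n_landing = 9L, is_large = is_large)
}

mk_spec <- function(soa = 400, direction = "right") {
  dplyr::bind_cols(
    tibble::tibble(trial_id = 1L, block = 1L, tool_end = "head",
                   orientation = "horizontal", soa_ms = soa,
                   cue_color = "green", direction = direction),
    epoch_times(soa, design_params()))
}

test_that("the first valid large saccade after the cue is selected", {
  spec <- mk_spec()
  # single large saccade 120 samples (400 ms) after the cue
  sel <- select_response_saccade(mk_events(spec$cue_on_ms + 120 * 1000 / 300),
                                 spec)
  expect_equal(sel$status, "valid")
  expect_equal(sel$srt_ms, 400)

  # a small saccade first, then the large one: the large one is selected
  ev <- dplyr::bind_rows(
    mk_events(spec$cue_on_ms + 150, is_large = FALSE),
    mk_events(spec$cue_on_ms + 350))
  sel2 <- select_response_saccade(ev, spec)
  expect_equal(sel2$status, "valid")
  expect_equal(sel2$srt_ms, 350)

  # 40 ms latency is anticipatory
  sel3 <- select_response_saccade(mk_events(spec$cue_on_ms + 40), spec)
  expect_equal(sel3$status, "anticipatory")
  expect_null(sel3$event)

  # wrong direction with the check enabled
  sel4 <- select_response_saccade(
    mk_events(spec$cue_on_ms + 300, direction = "left", landing_x = -12),
    spec)
  expect_equal(sel4$status, "wrong_direction")
  sel5 <- select_response_saccade(
    mk_events(spec$cue_on_ms + 300, direction = "left", landing_x = -12),
    spec, p = metrics_params(direction_check = FALSE))
  expect_equal(sel5$status, "valid")

  # no events at all
  sel6 <- select_response_saccade(mk_events(numeric(0))[0, ], spec)
  expect_equal(sel6$status, "no_saccade")
  sel7 <- select_response_saccade(mk_events(numeric(0))[0, ], spec,
                                  any_blink = TRUE)
  expect_equal(sel7$status, "blink_contaminated")
})

test_that("saccadic error is the Euclidean distance to the horizontal target", {
  expect_equal(compute_error(12, 0, "right"), 0)
  expect_equal(compute_error(11, 0, "right"), 1)
  expect_equal(compute_error(12, 0.5, "right"), 0.5)
  expect_equal(compute_error(-12, 0, "left"), 0)
  expect_equal(compute_error(-9, 4, "left"), 5)
})

test_that("subject aggregation rounds error means to 0.03 degrees, ties up", {
  res <- tibble::tibble(
    trial_id = 1:4, tool_end = "head", orientation = "horizontal",
    soa_ms = 400, direction = "right",
    srt_ms = c(400, 410, 420, NA),
    error_deg = c(0.142, 0.142, 0.142, NA),
    status = c("valid", "valid", "valid", "no_saccade"))
  agg <- aggregate_subject(res)
  expect_equal(agg$mean_error_deg, 0.15)  # 0.142 -> nearest 0.03 multiple
  expect_equal(agg$n_valid, 3)
  expect_equal(agg$mean_srt_ms, 410)

  res$error_deg <- c(0.03, 0.03, 0.03, NA)
  expect_equal(aggregate_subject(res)$mean_error_deg, 0.03)  # fixed point
  res$error_deg <- c(0.045, 0.045, 0.045, NA)
  expect_equal(aggregate_subject(res)$mean_error_deg, 0.06)  # tie rounds up

  # rounded means are always integer multiples of the quantum
  withr::with_seed(8, {
    res$error_deg <- c(runif(3), NA)
    m <- aggregate_subject(res)$mean_error_deg
    expect_equal(m %% 0.03, 0, tolerance = 1e-9)
  })
})

test_that("red trials never reach aggregation", {
  res <- tibble::tibble(
    trial_id = 1:3, tool_end = "red", orientation = "none", soa_ms = 400,
    direction = "none", srt_ms = NA_real_, error_deg = NA_real_,
    status = "red_excluded")
  agg <- aggregate_subject(res)
  expect_equal(nrow(agg), 0)
})

test_that("aggregation is invariant to trial order", {
  withr::with_seed(3, {
    res <- tibble::tibble(
      trial_id = 1:40,
      tool_end = sample(c("head", "handle"), 40, TRUE),
      orientation = "horizontal",
      soa_ms = sample(c(100, 400), 40, TRUE),
      direction = "right",
      srt_ms = rnorm(40, 400, 30),
      error_deg = abs(rnorm(40, 0.5, 0.2)),
      status = "valid")
  })
  a <- aggregate_subject(res)
  b <- aggregate_subject(res[sample(40), ])
  expect_equal(a, b)
})

test_that("subject exclusion drops high-missingness recordings (28 -> 26)", {
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:28),
    missing_frac = c(rep(0.02, 26), 0.5, 0.5))
  ex <- apply_subject_exclusions(subj)
  expect_equal(nrow(ex$retained), 26)
  expect_equal(nrow(ex$log), 2)
  expect_match(ex$log$reason[1], "missing-sample fraction")

  all_in <- apply_subject_exclusions(
    subj, metrics_params(subject_missing_exclusion_frac = 1))
  expect_equal(nrow(all_in$retained), 28)
  none <- apply_subject_exclusions(
    subj, metrics_params(subject_missing_exclusion_frac = 0))
  expect_equal(nrow(none$retained), 0)
})

test_that("every trial gets exactly one status and valid SRTs are bounded", {
  res <- process_cohort(n_subjects = 1, design = small_design(),
                        master_seed = 4)
  tr <- res$trials
  expect_equal(nrow(tr), 84)
  expect_equal(sum(table(tr$status)), 84)
  valid <- tr[tr$status == "valid", ]
  expect_true(all(valid$srt_ms >= 80))
  expect_true(all(valid$srt_ms <= 2000 - (500 + valid$soa_ms)))
  expect_true(all(is.na(tr$srt_ms[tr$status != "valid"])))
})

test_that("extracted SRT matches ground truth at sample precision (noise-free)", {
  res <- process_cohort(n_subjects = 1, design = small_design(),
                        lat = noiseless_latency(400),
                        noise = noiseless_noise(), master_seed = 5)
  valid <- res$trials[res$trials$status == "valid", ]
  expect_gt(nrow(valid), 70)
  err <- abs(valid$srt_ms - valid$true_srt_ms)
  expect_true(all(err <= 1000 / 300 + 1e-9))
})
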