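#' Design parameters for the saccadic precueing experiment
#'
#' Encodes the 3 x 4 within-subject design: a central fixation dot changes
#' color (the cue) at a variable stimulus onset asynchrony (SOA) after a tool
#' image appears in the background; blue cues a leftward, green a rightward
#' 12-degree saccade, red cues no saccade. Trials are labelled by which tool
#' end (head, handle, or neither for control objects) lies on the cued side.
#'
#' The defaults reproduce the published session structure: 10 blocks of 84
#' trials; 320 head-congruent, 320 handle-congruent, 160 control and 40 red
#' (catch) trials; SOAs of 100, 200, 400 or 600 ms with red trials always at
#' 400 ms; 500 ms fixation, 1000 ms image display, 500 ms return phase.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param n_head,n_handle,n_control,n_red Per-condition trial totals; must sum
#'   to `n_blocks * trials_per_block`.
#' @param soas SOA levels in ms between image onset and cue.
#' @param red_soa SOA used on every red (no-saccade) trial, ms.
#' @param fixation_ms,image_ms,return_ms Epoch durations in ms.
#' @param target_ecc_deg Horizontal target eccentricity, degrees.
#' @param oblique_frac Fraction of head/handle trials shown at oblique
#'   orientation (control objects are always horizontal).
#' @param cue_map Named character vector mapping cue color to saccade
#'   direction; must be a bijection over blue/green/red.
#' @param rng_seed Integer seed used by [build_schedule()] to shuffle trials.
#' @param block_balanced If `TRUE`, shuffle within blocks so each block holds
#'   an equal share of every condition; default shuffles the whole session.
#' @return A list of class `design_params`.
#' @examples
#' p <- design_params()
#' sched <- build_schedule(p)
#' dplyr::count(sched, tool_end)
#' @export
design_params <- function(n_blocks = 10, trials_per_block = 84,
                          n_head = 320, n_handle = 320, n_control = 160,
                          n_red = 40,
                          soas = c(100, 200, 400, 600), red_soa = 400,
                          fixation_ms = 500, image_ms = 1000, return_ms = 500,
                          target_ecc_deg = 12, oblique_frac = 0.5,
                          cue_map = c(blue = "left", green = "right",
                                      red = "none"),
                          rng_seed = 1L, block_balanced = FALSE) {
  p <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_head = as.integer(n_head), n_handle = as.integer(n_handle),
    n_control = as.integer(n_control), n_red = as.integer(n_red),
    soas = as.numeric(soas), red_soa = as.numeric(red_soa),
    fixation_ms = as.numeric(fixation_ms), image_ms = as.numeric(image_ms),
    return_ms = as.numeric(return_ms),
    target_ecc_deg = as.numeric(target_ecc_deg),
    oblique_frac = as.numeric(oblique_frac),
    cue_map = cue_map, rng_seed = as.integer(rng_seed),
    block_balanced = isTRUE(block_balanced)
  )
  class(p) <- "design_params"
  validate_design_params(p)
  p
}

validate_design_params <- function(p) {
  total <- p$n_head + p$n_handle + p$n_control + p$n_red
  if (total != p$n_blocks * p$trials_per_block) {
    stop_config(sprintf(
      "condition totals violate n_head + n_handle + n_control + n_red == n_blocks * trials_per_block (%d + %d + %d + %d != %d * %d)",
      p$n_head, p$n_handle, p$n_control, p$n_red,
      p$n_blocks, p$trials_per_block))
  }
  if (any(p$soas <= 0) || any(p$soas >= p$image_ms)) {
    stop_config("every SOA must be strictly positive and shorter than image_ms")
  }
  if (!setequal(names(p$cue_map), c("blue", "green", "red")) ||
      anyDuplicated(p$cue_map) > 0) {
    stop_config("cue_map must be a bijection over {blue, green, red}")
  }
  if (!(p$red_soa %in% p$soas)) {
    stop_config("red_soa must be one of the SOA levels")
  }
  if (p$oblique_frac < 0 || p$oblique_frac > 1) {
    stop_config("oblique_frac must lie in [0, 1]")
  }
  invisible(p)
}

#' Trial epoch timestamps
#'
#' Computes the five epoch timestamps of one trial, in ms relative to trial
#' start: fixation onset (0), image onset (after fixation), cue onset (image
#' onset + SOA), image offset, and trial end (after the return phase).
#'
#' @param soa_ms SOA of the trial in ms (vectorised).
#' @param params A [design_params()] object.
#' @return A tibble with columns `fixation_on_ms`, `image_on_ms`, `cue_on_ms`,
#'   `image_off_ms`, `trial_end_ms`.
#' @examples
#' epoch_times(400, design_params())  # cue at 900 ms, trial ends at 2000 ms
#' @export
epoch_times <- function(soa_ms, params = design_params()) {
  tibble::tibble(
    fixation_on_ms = 0,
    image_on_ms = params$fixation_ms,
    cue_on_ms = params$fixation_ms + soa_ms,
    image_off_ms = params$fixation_ms + params$image_ms,
    trial_end_ms = params$fixation_ms + params$image_ms + params$return_ms
  )
}

#' Build the randomized trial schedule
#'
#' Expands the per-condition totals into one row per trial, balances left and
#' right cues within every non-red condition cell, splits head/handle trials
#' between horizontal and oblique orientations, and shuffles the order with
#' the seed in `params`. The same seed always yields the same schedule.
#'
#' @param params A [design_params()] object.
#' @return A tibble with one row per trial: `trial_id`, `block`, `tool_end`,
#'   `orientation`, `soa_ms`, `cue_color`, `direction`, plus the epoch columns
#'   of [epoch_times()].
#' @export
build_schedule <- function(params = design_params()) {
  validate_design_params(params)
  dir_map <- stats::setNames(names(params$cue_map), params$cue_map)

  cell_rows <- function(tool_end, n_total) {
    n_soa <- length(params$soas)
    if (n_total %% (n_soa * 2L) != 0) {
      stop_config(sprintf(
        "%s trial count (%d) is not divisible by soas x directions (%d)",
        tool_end, n_total, n_soa * 2L))
    }
    per <- n_total %/% (n_soa * 2L)
    g <- tidyr::expand_grid(soa_ms = params$soas,
                            direction = c("left", "right"))
    g <- g[rep(seq_len(nrow(g)), each = per), ]
    g$tool_end <- tool_end
    g
  }

  split_orientation <- function(df, frac_oblique) {
    # deterministic split within each soa x direction cell
    df %>%
      dplyr::group_by(.data$soa_ms, .data$direction) %>%
      dplyr::mutate(orientation = as.character(ifelse(
        dplyr::row_number() <= round((1 - frac_oblique) * dplyr::n()),
        "horizontal", "oblique"))) %>%
      dplyr::ungroup()
  }

  head_df <- split_orientation(cell_rows("head", params$n_head),
                               params$oblique_frac)
  handle_df <- split_orientation(cell_rows("handle", params$n_handle),
                                 params$oblique_frac)
  control_df <- cell_rows("control", params$n_control)
  control_df$orientation <- "horizontal"  # control items have no oblique form
  red_df <- tibble::tibble(
    soa_ms = rep(params$red_soa, params$n_red),
    direction = "none", tool_end = "red", orientation = "none")

  all_df <- dplyr::bind_rows(head_df, handle_df, control_df, red_df)
  all_df$cue_color <- unname(dir_map[all_df$direction])

  ord <- withr::with_seed(params$rng_seed, {
    n <- nrow(all_df)
    if (params$block_balanced) {
      # round-robin each condition across blocks, then shuffle within block
      perm <- sample.int(n)
      cond <- all_df$tool_end[perm]
      blk <- integer(n)
      for (cn in unique(cond)) {
        w <- which(cond == cn)
        blk[w] <- rep(seq_len(params$n_blocks), length.out = length(w))
      }
      perm[order(blk, sample.int(n))]
    } else {
      sample.int(n)
    }
  })
  all_df <- all_df[ord, ]

  n <- nrow(all_df)
  all_df$trial_id <- seq_len(n)
  all_df$block <- rep(seq_len(params$n_blocks),
                      each = params$trials_per_block)[seq_len(n)]
  dplyr::bind_cols(
    all_df[, c("trial_id", "block", "tool_end", "orientation",
               "soa_ms", "cue_color", "direction")],
    epoch_times(all_df$soa_ms, params)
  )
}

#' Validate a trial schedule against its design
#'
#' Checks every structural invariant of the design (per-condition totals,
#' epoch arithmetic, red-trial rules, control orientation, left/right
#' balance) and reports violations as data rather than raising errors.
#'
#' @param schedule A schedule tibble as from [build_schedule()].
#' @param params The [design_params()] the schedule should satisfy.
#' @return A tibble of violations (`rule`, `detail`); zero rows when the
#'   schedule is fully consistent.
#' @export
validate_schedule <- function(schedule, params = design_params()) {
  v <- list()
  add <- function(rule, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(rule = rule, detail = detail)
  }

  expect_n <- c(head = params$n_head, handle = params$n_handle,
                control = params$n_control, red = params$n_red)
  got <- table(factor(schedule$tool_end, levels = names(expect_n)))
  for (cond in names(expect_n)) {
    if (got[[cond]] != expect_n[[cond]]) {
      add("condition_count", sprintf("%s: expected %d, found %d",
                                     cond, expect_n[[cond]], got[[cond]]))
    }
  }
  if (nrow(schedule) != params$n_blocks * params$trials_per_block) {
    add("total_count", sprintf("expected %d trials, found %d",
                               params$n_blocks * params$trials_per_block,
                               nrow(schedule)))
  }

  bad_red <- schedule$tool_end == "red" &
    (schedule$direction != "none" | schedule$soa_ms != params$red_soa)
  if (any(bad_red)) {
    add("red_trial", sprintf(
      "trials %s: red trials must have direction none and soa %g",
      paste(schedule$trial_id[bad_red], collapse = ","), params$red_soa))
  }
  bad_ctrl <- schedule$tool_end == "control" &
    schedule$orientation != "horizontal"
  if (any(bad_ctrl)) {
    add("control_orientation", sprintf(
      "trials %s: control items are horizontal only",
      paste(schedule$trial_id[bad_ctrl], collapse = ",")))
  }
  bad_soa <- !(schedule$soa_ms %in% params$soas)
  if (any(bad_soa)) {
    add("soa_level", sprintf("trials %s: soa not a design level",
                             paste(schedule$trial_id[bad_soa], collapse = ",")))
  }

  et <- epoch_times(schedule$soa_ms, params)
  for (col in names(et)) {
    if (!isTRUE(all.equal(schedule[[col]], et[[col]]))) {
      add("epoch_times", sprintf("column %s inconsistent with design", col))
    }
  }

  bal <- schedule %>%
    dplyr::filter(.data$tool_end != "red") %>%
    dplyr::count(.data$tool_end, .data$soa_ms, .data$direction) %>%
    dplyr::group_by(.data$tool_end, .data$soa_ms) %>%
    dplyr::summarise(diff = max(.data$n) - min(.data$n),
                     k = dplyr::n(), .groups = "drop")
  if (any(bal$diff != 0 | bal$k != 2)) {
    add("direction_balance",
        "left/right cues unbalanced within a tool_end x soa cell")
  }

  if (length(v) == 0) {
    tibble::tibble(rule = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Write or read a schedule as a delimited table
#'
#' @param schedule Schedule tibble.
#' @param path File path (CSV).
#' @return `read_schedule()` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
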