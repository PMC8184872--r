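#' Pipeline configuration
#'
#' Bundles every stage's parameters with a master seed and an output
#' directory. Validation is pre-flight: nested parameter objects enforce
#' their own invariants at construction, and cross-parameter consistency is
#' checked here before any computation starts.
#'
#' @param out_dir Run directory for stage outputs.
#' @param n_subjects Number of simulated subjects.
#' @param design,kinematics,latency,noise,filter,blink,detection,metrics
#'   Stage parameter objects (defaults used when `NULL`).
#' @param master_seed Master integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_subjects = 2,
                            design = design_params(),
                            kinematics = kinematics_params(),
                            latency = latency_model(),
                            noise = noise_params(),
                            filter = filter_params(),
                            blink = blink_params(),
                            detection = detection_params(),
                            metrics = metrics_params(),
                            master_seed = 1L) {
  cfg <- list(out_dir = out_dir, n_subjects = as.integer(n_subjects),
              design = design, kinematics = kinematics, latency = latency,
              noise = noise, filter = filter, blink = blink,
              detection = detection, metrics = metrics,
              master_seed = as.integer(master_seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  validate_design_params(cfg$design)
  if (cfg$detection$theta_all > cfg$detection$theta_big) {
    stop_config("detection thresholds must satisfy theta_all <= theta_big")
  }
  if (cfg$n_subjects < 1) stop_config("n_subjects must be at least 1")
  if (cfg$latency$min_latency < 0) stop_config("min_latency must be >= 0")
  invisible(cfg)
}

#' Run the full pipeline (simulate, preprocess, detect, metrics, infer)
#'
#' Executes every stage in order, writes each stage's output as plain
#' delimited text under `config$out_dir`, and records a JSON manifest with
#' MD5 checksums. Rerunning with an identical configuration and seed
#' reproduces identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage_file <- function(stage, name) {
    f <- file.path(config$out_dir, name)
    paths[[stage]] <<- c(paths[[stage]], f)
    f
  }

  # stage 1: design (the first subject's schedule documents the structure)
  p1 <- config$design
  p1$rng_seed <- child_seed(config$master_seed, 1L) + 1L
  write_schedule(build_schedule(p1), stage_file("design", "design.csv"))

  # stages 2-4: simulate + preprocess + detect + metrics, streamed per
  # subject through the same cores as the stage functions
  res <- process_cohort(
    n_subjects = config$n_subjects, design = config$design,
    k = config$kinematics, lat = config$latency, noise = config$noise,
    fp = config$filter, bp = config$blink, dp = config$detection,
    mp = config$metrics, master_seed = config$master_seed)
  readr::write_csv(res$subjects,
                   stage_file("simulate", "subjects.csv"))
  readr::write_csv(res$trials,
                   stage_file("metrics", "trial_results.csv"))
  readr::write_csv(res$summaries,
                   stage_file("aggregate", "subject_summaries.csv"))

  # stage 5: inference
  excl <- apply_subject_exclusions(res$subjects, config$metrics)
  kept <- res$summaries %>%
    dplyr::filter(.data$subject_id %in% excl$retained$subject_id,
                  .data$tool_end %in% c("head", "handle", "control"))
  fit <- if (length(unique(kept$subject_id)) >= 2) {
    rm_anova(kept, "mean_srt_ms", within = c("tool_end", "soa_ms"))
  } else NULL
  if (!is.null(fit)) {
    readr::write_csv(tidy(fit), stage_file("infer", "anova_srt.csv"))
  } else {
    readr::write_csv(tibble::tibble(note = "too few subjects for ANOVA"),
                     stage_file("infer", "anova_srt.csv"))
  }

  all_files <- unlist(paths, use.names = FALSE)
  manifest <- list(
    master_seed = config$master_seed,
    n_subjects = config$n_subjects,
    stages = lapply(paths, function(fs) {
      lapply(fs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      })
    }),
    n_trials = nrow(res$trials),
    status_counts = as.list(table(res$trials$status)),
    excluded_subjects = excl$log$subject_id
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(results = res, anova = fit, exclusions = excl,
                 manifest = manifest_path))
}

#' Summarise an existing pipeline run
#'
#' Read-only: verifies the manifest's checksums and reports trial-status
#' counts, per-condition mean SRT, and the ANOVA table. Never recomputes
#' any stage.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A list: `manifest`, `checksum_ok` (named logical), `status_counts`,
#'   `condition_means`, `anova`.
#' @export
describe_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest found in %s", run_dir))
  }
  manifest <- jsonlite::read_json(manifest_path)
  checks <- c()
  for (stage in manifest$stages) {
    for (entry in stage) {
      f <- file.path(run_dir, entry$file)
      ok <- file.exists(f) &&
        identical(unname(tools::md5sum(f)), entry$md5)
      checks[entry$file] <- ok
    }
  }
  summaries <- readr::read_csv(file.path(run_dir, "subject_summaries.csv"),
                               show_col_types = FALSE)
  cond <- summaries %>%
    dplyr::filter(.data$tool_end != "red") %>%
    dplyr::group_by(.data$tool_end) %>%
    dplyr::summarise(mean_srt_ms = mean(.data$mean_srt_ms),
                     .groups = "drop")
  anova_tab <- readr::read_csv(file.path(run_dir, "anova_srt.csv"),
                               show_col_types = FALSE)
  list(manifest = manifest, checksum_ok = checks,
       status_counts = manifest$status_counts,
       condition_means = cond, anova = anova_tab)
}

#' Recover the tool-end latency effect end-to-end
#'
#' Convenience wrapper for the package's headline computation: simulate a
#' cohort under the calibrated latency model, run preprocessing, saccade
#' detection and SRT extraction, and return each subject's mean SRT per
#' tool-end condition together with the across-subject handle-minus-head
#' difference.
#'
#' @param n_subjects Cohort size.
#' @param master_seed Master seed.
#' @param design,k,lat,noise,fp,bp,dp,mp Parameter objects.
#' @return A list: `subject_means` (subject x tool_end tibble),
#'   `handle_minus_head_ms` (scalar), `cohort` (full [process_cohort()]
#'   output).
#' @export
recover_toolend_effect <- function(n_subjects = 26, master_seed = 1L,
                                   design = design_params(),
                                   k = kinematics_params(),
                                   lat = latency_model(),
                                   noise = noise_params(),
                                   fp = filter_params(),
                                   bp = blink_params(),
                                   dp = detection_params(),
                                   mp = metrics_params()) {
  res <- process_cohort(n_subjects, design, k, lat, noise, fp, bp, dp, mp,
                        master_seed)
  subject_means <- res$trials %>%
    dplyr::filter(.data$status == "valid") %>%
    dplyr::group_by(.data$subject_id, .data$tool_end) %>%
    dplyr::summarise(mean_srt_ms = mean(.data$srt_ms), .groups = "drop")
  wide <- tidyr::pivot_wider(subject_means, names_from = "tool_end",
                             values_from = "mean_srt_ms")
  diff_ms <- mean(wide$handle - wide$head)
  list(subject_means = subject_means, handle_minus_head_ms = diff_ms,
       cohort = res)
}
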