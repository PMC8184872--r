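#' Plot a gaze trace with detected saccades
#'
#' Horizontal and vertical position against time, with missing stretches
#' blanked and detected saccade onsets marked.
#'
#' @param trace Gaze trace tibble (one trial works best).
#' @param events Optional event tibble from [detect_saccades()].
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(trace, events = NULL) {
  long <- tidyr::pivot_longer(trace, c("x", "y"), names_to = "axis",
                              values_to = "position")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms,
                                          y = .data$position,
                                          color = .data$axis)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = "gaze position (deg)",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = events, ggplot2::aes(xintercept = .data$onset_ms),
      linetype = "dashed", alpha = 0.6)
  }
  p
}

#' Plot condition means with between-subject error bars
#'
#' @param summaries Subject-level cell means (as from [process_cohort()]'s
#'   `summaries`, with a `subject_id` column).
#' @param dv Column to plot (`"mean_srt_ms"` or `"mean_error_deg"`).
#' @param by Condition column on the x axis.
#' @return A ggplot object (mean with SEM error bars).
#' @export
plot_condition_means <- function(summaries, dv = "mean_srt_ms",
                                 by = "tool_end") {
  agg <- summaries %>%
    dplyr::group_by(.data$subject_id, .data[[by]]) %>%
    dplyr::summarise(v = mean(.data[[dv]]), .groups = "drop") %>%
    dplyr::group_by(.data[[by]]) %>%
    dplyr::summarise(mean = mean(.data$v),
                     sem = stats::sd(.data$v) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[by]], y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = dv) +
    ggplot2::theme_minimal()
}

#' Autoplot method for repeated-measures ANOVA objects
#'
#' Dot plot of each effect's generalized eta squared, annotated with its
#' Greenhouse-Geisser corrected p-value.
#'
#' @param object An `rm_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_anova <- function(object, ...) {
  eff <- object$effects
  eff$label <- sprintf("p[GG] = %.3g", eff$p_gg)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$eta_g2, y = .data$effect)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = expression(eta[G]^2), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
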