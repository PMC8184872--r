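#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One row per effect with F, corrected dfs, epsilon, p-values and
#'   generalized eta squared.
#' @export
tidy.rm_anova <- function(x, ...) {
  x$effects
}

#' One-line model summary for a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: subject count, cell count, total and
#'   subject-related sums of squares.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_effects = nrow(x$effects),
    ss_total = x$ss_total,
    ss_subject = x$ss_subject,
    ss_subject_related = x$ss_subject_related
  )
}
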