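#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor estimated from the sample covariance of the
#' within-subject condition scores: with `S_c` the double-centered
#' covariance matrix, `epsilon = tr(S_c)^2 / ((k - 1) * tr(S_c^2))`, clipped
#' to its theoretical range `[1 / (k - 1), 1]`.
#'
#' @param cell_matrix Numeric matrix, subjects in rows, conditions in
#'   columns (at least two conditions).
#' @return Epsilon, a scalar in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(cell_matrix) {
  k <- ncol(cell_matrix)
  if (k < 2) stop_config("gg_epsilon needs at least 2 conditions")
  S <- stats::cov(cell_matrix)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
  min(max(eps, 1 / (k - 1)), 1)
}

# Orthonormal contrast rows for a k-level factor (rows span the space
# orthogonal to the unit vector).
orthonormal_contrasts <- function(k) {
  q <- qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))
  t(q[, -1, drop = FALSE])
}

# Epsilon for an arbitrary effect in a multi-factor within design: project
# the per-subject cell vectors onto the effect's orthonormal contrast space
# (Kronecker product over factors) and apply the trace formula.
gg_epsilon_effect <- function(cell_matrix, levels_per_factor, effect_idx) {
  M <- matrix(1, 1, 1)
  for (j in seq_along(levels_per_factor)) {
    kj <- levels_per_factor[j]
    block <- if (j %in% effect_idx) orthonormal_contrasts(kj)
    else matrix(1 / sqrt(kj), 1, kj)
    # cells are ordered with factor 1 varying fastest; keep it innermost
    M <- kronecker(block, M)
  }
  d <- nrow(M)
  if (d < 2) return(1)  # single-df effects need no correction
  E <- M %*% stats::cov(cell_matrix) %*% t(M)
  eps <- sum(diag(E))^2 / (d * sum(E * E))
  min(max(eps, 1 / d), 1)
}

# Balanced full within-subject SS decomposition on an array whose dims are
# (factor levels ..., subjects). Returns named SS/df for every term.
ss_decompose <- function(arr) {
  dims <- dim(arr)
  m <- length(dims)          # last margin is subjects
  grand <- mean(arr)
  terms <- list()
  all_subsets <- function(v) {
    unlist(lapply(seq_along(v), function(s) {
      utils::combn(v, s, simplify = FALSE)
    }), recursive = FALSE)
  }
  subsets <- all_subsets(seq_len(m))
  effect_of <- new.env()
  get_effect <- function(T) {
    key <- paste(T, collapse = ",")
    if (!is.null(effect_of[[key]])) return(effect_of[[key]])
    a <- apply(arr, T, mean) - grand
    if (length(T) > 1) {
      for (S in all_subsets(T)) {
        if (length(S) < length(T)) {
          sub <- get_effect(S)
          # broadcast the lower-order effect over T's grid
          a <- a - aperm_expand(sub, dims[T], match(S, T))
        }
      }
    }
    effect_of[[key]] <- a
    a
  }
  out <- list()
  for (T in subsets) {
    a <- get_effect(T)
    reps <- prod(dims[setdiff(seq_len(m), T)])
    df <- prod(dims[T] - 1)
    out[[paste(T, collapse = ",")]] <- list(ss = reps * sum(a^2), df = df,
                                            idx = T)
  }
  out
}

# Expand an effect array defined on dims[sub_pos] of a target grid
# perm_dims, replicating over the remaining dims.
aperm_expand <- function(sub, perm_dims, sub_pos) {
  full <- array(0, dim = c(perm_dims[sub_pos],
                           perm_dims[setdiff(seq_along(perm_dims), sub_pos)]))
  full[] <- as.vector(sub)  # recycles over trailing (replicated) dims
  aperm(full, order(c(sub_pos, setdiff(seq_along(perm_dims), sub_pos))))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Full within-subject sums-of-squares decomposition for a balanced design
#' with one observation per subject per cell. Each effect is tested against
#' its own effect-by-subject error stratum; a Greenhouse-Geisser epsilon is
#' estimated per effect from the covariance of the within-subject scores and
#' applied to the degrees of freedom of every effect with more than one
#' numerator df. Generalized eta squared uses all subject-related variance
#' (subject SS plus every error stratum) in its denominator, the convention
#' for designs in which all factors are manipulated.
#'
#' @param data Long-format data frame / tibble.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject-identifier column.
#' @return An object of class `rm_anova`; its `effects` element is a tibble
#'   with `effect`, `df1`, `df2` (uncorrected), `ss_effect`, `ss_error`,
#'   `F`, `epsilon_gg`, `df1_gg`, `df2_gg`, `p_uncorrected`, `p_gg`,
#'   `eta_g2`. Use [generics::tidy()] / [generics::glance()].
#' @examples
#' d <- tidyr::expand_grid(subject_id = factor(1:6), cond = c("a", "b", "c"))
#' d$dv <- rnorm(nrow(d)) + as.integer(factor(d$cond))
#' fit <- rm_anova(d, "dv", within = "cond")
#' tidy(fit)
#' @export
rm_anova <- function(data, dv, within, subject = "subject_id") {
  df <- tibble::as_tibble(data)
  need <- c(dv, within, subject)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste("missing columns:",
                                    paste(miss, collapse = ", ")))
  for (w in within) df[[w]] <- factor(df[[w]])
  df[[subject]] <- factor(df[[subject]])

  lv <- lapply(df[within], levels)
  k_each <- vapply(lv, length, 1L)
  subj_lv <- levels(df[[subject]])
  n_subj <- length(subj_lv)
  if (n_subj < 2) abort("rm_anova needs at least 2 subjects")
  n_cells <- prod(k_each)
  counts <- df %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(within, subject))))
  if (nrow(counts) != n_cells * n_subj || any(counts$n != 1)) {
    full <- tidyr::expand_grid(!!!stats::setNames(
      c(lv, list(subj_lv)), c(within, subject)))
    missing_cells <- dplyr::anti_join(
      full, df[, c(within, subject)], by = c(within, subject))
    abort(paste0(
      "unbalanced within-subject table: need exactly one value per cell; ",
      if (nrow(missing_cells) > 0) {
        paste("missing cells e.g.",
              paste(utils::capture.output(print(utils::head(
                as.data.frame(missing_cells), 3))), collapse = " "))
      } else "duplicated cells present"))
  }

  # arrange into (k1, ..., km, n_subjects) array
  ord <- do.call(order, c(
    lapply(rev(c(within, subject)), function(cn) df[[cn]])))
  arr_df <- df[ord, ]
  arr <- array(arr_df[[dv]], dim = c(unname(k_each), n_subj))

  dec <- ss_decompose(arr)
  m <- length(within)
  subj_dim <- m + 1L

  # cell matrix: subjects x cells (cells vary fastest over factor 1)
  cell_mat <- t(matrix(arr, nrow = n_cells, ncol = n_subj))

  is_subject_term <- function(t) subj_dim %in% t$idx
  ss_subject_related <- sum(vapply(dec, function(t) {
    if (is_subject_term(t)) t$ss else 0
  }, 1.0))

  effect_terms <- Filter(function(t) !is_subject_term(t), dec)
  rows <- lapply(effect_terms, function(t) {
    err <- dec[[paste(sort(c(t$idx, subj_dim)), collapse = ",")]]
    Fv <- (t$ss / t$df) / (err$ss / err$df)
    eps <- gg_epsilon_effect(cell_mat, unname(k_each), t$idx)
    df1 <- t$df; df2 <- err$df
    tibble::tibble(
      effect = paste(within[t$idx], collapse = ":"),
      df1 = df1, df2 = df2, ss_effect = t$ss, ss_error = err$ss,
      F = Fv, epsilon_gg = eps,
      df1_gg = eps * df1, df2_gg = eps * df2,
      p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
      eta_g2 = t$ss / (t$ss + ss_subject_related))
  })
  effects <- dplyr::bind_rows(rows)

  out <- list(effects = effects, dv = dv, within = within,
              subject = subject, n_subjects = n_subj,
              ss_subject = dec[[as.character(subj_dim)]]$ss,
              ss_subject_related = ss_subject_related,
              ss_total = sum(vapply(dec, function(t) t$ss, 1.0)),
              decomposition = dec)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s' (%d subjects)\n",
              x$dv, x$n_subjects))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf(
      "  %-20s F(%.2f, %.2f) = %.3f, p = %.4g (G-G), eps = %.3f, eta_G2 = %.4f\n",
      eff$effect[i], eff$df1_gg[i], eff$df2_gg[i], eff$F[i],
      eff$p_gg[i], eff$epsilon_gg[i], eff$eta_g2[i]))
  }
  invisible(x)
}

#' Generalized eta squared from a sums-of-squares decomposition
#'
#' `eta_G2 = SS_effect / (SS_effect + SS_subject-related)`, where the
#' denominator pools the subject main SS and every effect-by-subject error
#' stratum.
#'
#' @param ss_effect Effect sum of squares.
#' @param ss_subject_related Total subject-related sum of squares.
#' @return Effect size in `[0, 1]`.
#' @examples
#' generalized_eta_squared(2, 38)  # 0.05
#' @export
generalized_eta_squared <- function(ss_effect, ss_subject_related) {
  ss_effect / (ss_effect + ss_subject_related)
}

#' Paired t-test between two within-subject levels
#'
#' Classical paired t on subject cell means, with a guard for the
#' degenerate zero-variance case (the statistic is reported as a signed
#' infinity with `degenerate = TRUE` and p of 0, or t = 0 / p = 1 when the
#' difference is identically zero).
#'
#' @param data Long-format data.
#' @param dv Dependent-variable column name.
#' @param within Factor column name.
#' @param level_a,level_b Levels to compare (`mean_diff = a - b`).
#' @param subject Subject column name.
#' @return One-row tibble: `pair`, `t`, `df`, `mean_diff`, `p`,
#'   `degenerate`.
#' @export
paired_t <- function(data, dv, within, level_a, level_b,
                     subject = "subject_id") {
  if (identical(level_a, level_b)) {
    n <- length(unique(data[[subject]]))
    return(tibble::tibble(pair = paste(level_a, "-", level_b), t = 0,
                          df = n - 1L, mean_diff = 0, p = 1,
                          degenerate = FALSE))
  }
  df <- tibble::as_tibble(data)
  wide <- df %>%
    dplyr::filter(.data[[within]] %in% c(level_a, level_b)) %>%
    dplyr::group_by(.data[[subject]], .data[[within]]) %>%
    dplyr::summarise(v = mean(.data[[dv]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = "v")
  if (!all(c(level_a, level_b) %in% names(wide)) ||
      anyNA(wide[[level_a]]) || anyNA(wide[[level_b]])) {
    abort("both levels must be present for every subject")
  }
  d <- wide[[level_a]] - wide[[level_b]]
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(tibble::tibble(pair = paste(level_a, "-", level_b), t = 0,
                            df = n - 1L, mean_diff = 0, p = 1,
                            degenerate = TRUE))
    }
    return(tibble::tibble(pair = paste(level_a, "-", level_b),
                          t = sign(md) * Inf, df = n - 1L, mean_diff = md,
                          p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(wide[[level_a]], wide[[level_b]], paired = TRUE)
  tibble::tibble(pair = paste(level_a, "-", level_b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 mean_diff = md, p = tt$p.value, degenerate = FALSE)
}

#' All pairwise paired t-tests for one factor
#'
#' Raw p-values match the classical per-pair tests; Holm-adjusted values
#' are added across the family.
#'
#' @inheritParams paired_t
#' @return Tibble with one row per pair (`p_raw`, `p_holm`).
#' @export
pairwise_t <- function(data, dv, within, subject = "subject_id") {
  lv <- unique(as.character(data[[within]]))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- dplyr::bind_rows(lapply(pairs, function(pr) {
    paired_t(data, dv, within, pr[1], pr[2], subject)
  }))
  out %>%
    dplyr::rename(p_raw = "p") %>%
    dplyr::mutate(p_holm = stats::p.adjust(.data$p_raw, method = "holm"))
}
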