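test_that("one-way repeated-measures ANOVA matches brute-force summation", {
  withr::with_seed(7, {
    mat <- matrix(rnorm(12, 400, 20), nrow = 4, ncol = 3) +
      outer(rep(0, 4), c(0, 5, 12))
  })
  d <- long_from_matrix(mat)
  fit <- rm_anova(d, "dv", within = "cond")
  want <- brute_rm_anova_1w(mat)

  eff <- tidy(fit)
  expect_equal(eff$F, want$F, tolerance = 1e-10)
  expect_equal(eff$ss_effect, want$ss_cond, tolerance = 1e-10)
  expect_equal(eff$ss_error, want$ss_err, tolerance = 1e-10)
  expect_equal(eff$eta_g2, want$eta_g2, tolerance = 1e-10)
  expect_equal(eff$df1, want$df1)
  expect_equal(eff$df2, want$df2)
  expect_equal(glance(fit)$ss_total, want$ss_total, tolerance = 1e-10)

  # independent library cross-check on the same data
  a <- stats::aov(dv ~ cond + Error(subject_id / cond), data = d)
  F_aov <- summary(a)[["Error: subject_id:cond"]][[1]]["cond", "F value"]
  expect_equal(eff$F, F_aov, tolerance = 1e-8)
})

test_that("two-factor decomposition agrees with aov error strata", {
  withr::with_seed(21, {
    d <- tidyr::expand_grid(subject_id = factor(1:8),
                            A = factor(c("a1", "a2", "a3")),
                            B = factor(c("b1", "b2", "b3", "b4")))
    d$dv <- rnorm(nrow(d), 400, 25) +
      5 * (d$A == "a2") + 10 * (d$B == "b3") +
      4 * (d$A == "a3") * (d$B == "b1")
  })
  fit <- rm_anova(d, "dv", within = c("A", "B"))
  eff <- tidy(fit)

  a <- stats::aov(dv ~ A * B + Error(subject_id / (A * B)), data = d)
  s <- summary(a)
  F_A <- s[["Error: subject_id:A"]][[1]]["A", "F value"]
  F_B <- s[["Error: subject_id:B"]][[1]]["B", "F value"]
  F_AB <- s[["Error: subject_id:A:B"]][[1]]["A:B", "F value"]
  expect_equal(eff$F[eff$effect == "A"], F_A, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "B"], F_B, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "A:B"], F_AB, tolerance = 1e-8)
  expect_equal(eff$df1[eff$effect == "A:B"], 6)
  expect_equal(eff$df2[eff$effect == "A:B"], 42)

  # SS conservation across all strata
  dec <- fit$decomposition
  ss_sum <- sum(vapply(dec, function(t) t$ss, 1.0))
  grand <- mean(d$dv)
  expect_equal(ss_sum, sum((d$dv - grand)^2), tolerance = 1e-8)
})

test_that("Greenhouse-Geisser epsilon honors its bounds and exact cases", {
  withr::with_seed(13, {
    for (i in 1:20) {
      mat <- matrix(rnorm(30), 10, 3)
      e <- gg_epsilon(mat)
      expect_gte(e, 0.5)  # 1/(k-1) for k = 3
      expect_lte(e, 1)
    }
  })

  # exactly spherical sample covariance: epsilon == 1
  sph <- spherical_matrix(12, 3)
  expect_equal(gg_epsilon(sph), 1, tolerance = 1e-12)

  # identical columns plus iid noise: epsilon near 1
  withr::with_seed(5, {
    z <- rnorm(200)
    mat <- cbind(z, z, z) + matrix(rnorm(600, 0, 1), 200, 3)
  })
  expect_gt(gg_epsilon(mat), 0.9)

  # rank-one difference structure: epsilon pinned at the 1/(k-1) bound
  withr::with_seed(6, {
    z <- rnorm(40); w <- rnorm(40, 0, 3)
    mat1 <- cbind(z, z, z + w)
  })
  expect_equal(gg_epsilon(mat1), 0.5, tolerance = 1e-10)
})

test_that("corrected dfs are epsilon times the uncorrected (2, 50) pattern", {
  withr::with_seed(31, {
    mat <- matrix(rnorm(78, 400, 15), 26, 3)
  })
  fit <- rm_anova(long_from_matrix(mat), "dv", within = "cond")
  eff <- tidy(fit)
  expect_equal(eff$df1, 2)
  expect_equal(eff$df2, 50)
  expect_equal(eff$df1_gg, eff$epsilon_gg * 2)
  expect_equal(eff$df2_gg, eff$epsilon_gg * 50)
  # the published df mapping: epsilon 0.8 on (2, 50) gives (1.6, 40)
  expect_equal(0.8 * c(2, 50), c(1.6, 40))
})

test_that("p-value under G-G correction increases as epsilon decreases", {
  F <- 4.2
  eps <- seq(1, 0.5, by = -0.05)
  p <- stats::pf(F, eps * 2, eps * 50, lower.tail = FALSE)
  expect_true(all(diff(p) > 0))
})

test_that("generalized eta squared uses all subject-related variance", {
  expect_equal(generalized_eta_squared(2, 38), 0.05)
  expect_equal(generalized_eta_squared(0, 38), 0)
  expect_equal(generalized_eta_squared(5, 0), 1)
})

test_that("unbalanced tables are rejected naming the missing cells", {
  d <- long_from_matrix(matrix(rnorm(12), 4, 3))
  expect_error(rm_anova(d[-1, ], "dv", within = "cond"), "unbalanced")
  expect_error(rm_anova(dplyr::bind_rows(d, d[1, ]), "dv", within = "cond"),
               "unbalanced")
})

test_that("paired t handles the classical and degenerate cases", {
  withr::with_seed(17, {
    mat <- matrix(rnorm(52, 400, 12), 26, 2)
    mat[, 1] <- mat[, 1] + 9
  })
  d <- long_from_matrix(mat)
  res <- paired_t(d, "dv", "cond", "1", "2")
  expect_equal(res$df, 25)  # n - 1
  ref <- stats::t.test(mat[, 1], mat[, 2], paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(sign(res$mean_diff), sign(res$t))

  same <- paired_t(d, "dv", "cond", "1", "1")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # constant nonzero difference: capped with an explicit flag
  mat2 <- cbind(rnorm(10), 0)
  mat2[, 2] <- mat2[, 1] - 5
  dg <- paired_t(long_from_matrix(mat2), "dv", "cond", "1", "2")
  expect_true(dg$degenerate)
  expect_equal(dg$p, 0)
  expect_gt(dg$t, 0)

  pw <- pairwise_t(long_from_matrix(matrix(rnorm(30), 10, 3)), "dv", "cond")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_holm >= pw$p_raw))
})

test_that("a paper-scale latency effect is detected in most replications", {
  # latency-level power check: 9 ms head-handle shift, 26 subjects,
  # 320 trials per condition collapsed to cell means
  hits <- 0
  for (rep in 1:10) {
    withr::with_seed(700 + rep, {
      subj <- rnorm(26, 0, 54)
      cells <- tidyr::expand_grid(subject_id = factor(1:26),
                                  tool_end = c("head", "handle", "control"),
                                  soa = factor(c(100, 200, 400, 600)))
      mu <- c(head = 393, handle = 402, control = 402)[cells$tool_end]
      cells$dv <- mu + subj[as.integer(cells$subject_id)] +
        rnorm(nrow(cells), 0, 50 / sqrt(80))
    })
    fit <- rm_anova(cells, "dv", within = c("tool_end", "soa"))
    p <- tidy(fit)$p_gg[tidy(fit)$effect == "tool_end"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
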