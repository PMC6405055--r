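test_that("pooled t, df and Cohen's d match closed-form hand computation", {
  tt <- two_sample_t(c(1, 2, 3), c(2, 3, 4), variant = "pooled")
  # sp2 = 1, t = (2-3)/sqrt(1 * (1/3 + 1/3)) = -sqrt(3/2)
  expect_equal(tt$t, -sqrt(1.5), tolerance = 1e-12)
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$d, -1)
  expect_equal(tt$p, 2 * stats::pt(-sqrt(1.5), 4), tolerance = 1e-12)

  id <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_equal(id$d, 0)
})

test_that("one-sided p in the matching direction is half the two-sided p", {
  two <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  less <- two_sample_t(c(1, 2, 3), c(2, 3, 4), alternative = "less")
  expect_equal(less$p, two$p / 2, tolerance = 1e-12)
  greater <- two_sample_t(c(1, 2, 3), c(2, 3, 4), alternative = "greater")
  expect_equal(greater$p, 1 - two$p / 2, tolerance = 1e-12)
})

test_that("the Welch variant uses the Satterthwaite df formula", {
  set.seed(3)
  x <- rnorm(8, sd = 1); y <- rnorm(20, sd = 4)
  tt <- two_sample_t(x, y, variant = "welch")
  v1 <- var(x) / 8; v2 <- var(y) / 20
  df_hand <- (v1 + v2)^2 / (v1^2 / 7 + v2^2 / 19)
  t_hand <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  expect_equal(tt$df, df_hand, tolerance = 1e-10)
  expect_equal(tt$t, t_hand, tolerance = 1e-10)
})

test_that("pooled t is antisymmetric under group exchange", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(12, 1)
  a <- two_sample_t(x, y)
  b <- two_sample_t(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$d, -b$d)
  expect_equal(a$p, b$p)
})

test_that("degenerate zero-variance equal-mean samples give t = 0, p = 1", {
  tt <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_error(two_sample_t(c(1), c(2, 3)), "at least 2")
})

# independent sum-of-squares oracle for the one-way within-subject design
rm_anova_by_hand <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, df1 = k - 1, df2 = (n - 1) * (k - 1),
       eta = ss_cond / (ss_cond + ss_err))
}

test_that("rm-ANOVA F, dfs and partial eta^2 match the brute-force SS decomposition", {
  m <- cbind(a = c(3.1, 4.2, 2.8, 5.0), b = c(4.0, 5.1, 3.5, 6.2))
  hand <- rm_anova_by_hand(m)
  fit <- rm_anova(m)
  expect_equal(fit$F, hand$F, tolerance = 1e-10)
  expect_equal(fit$df1, hand$df1)
  expect_equal(fit$df2, hand$df2)
  expect_equal(fit$eta_sq, hand$eta, tolerance = 1e-10)
  expect_equal(fit$p, stats::pf(hand$F, hand$df1, hand$df2, lower.tail = FALSE),
               tolerance = 1e-10)

  set.seed(11)
  m4 <- matrix(rnorm(10 * 4), 10, 4,
               dimnames = list(NULL, c("w", "x", "y", "z")))
  hand4 <- rm_anova_by_hand(m4)
  fit4 <- rm_anova(m4)
  expect_equal(fit4$F, hand4$F, tolerance = 1e-10)
  expect_equal(fit4$eta_sq, hand4$eta, tolerance = 1e-10)
})

test_that("rm-ANOVA with equal cells returns F = 0, eta^2 = 0", {
  m <- matrix(5, 4, 3)
  fit <- rm_anova(m)
  expect_equal(fit$F, 0)
  expect_equal(fit$eta_sq, 0)
  expect_equal(fit$p, 1)
})

test_that("rm-ANOVA with two conditions satisfies F = t^2 of the paired t-test", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 2, sd = 2), 8, 2)
    fit <- rm_anova(m)
    tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("missing conditions drop subjects in complete-case mode, and Bonferroni never shrinks p", {
  set.seed(13)
  m <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1, 2] <- NA
  fit <- rm_anova(m)
  expect_equal(fit$n_subjects, 5)
  expect_equal(fit$n_dropped, 1)
  raw <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    ok <- stats::complete.cases(m[, pr])
    stats::t.test(m[ok, pr[1]], m[ok, pr[2]], paired = TRUE)$p.value
  }, 0)
  expect_equal(fit$pairwise$p_adj, pmin(1, raw * 3), tolerance = 1e-10)
  expect_true(all(fit$pairwise$p_adj >= raw))

  # single pair: adjusted = raw
  fit2 <- rm_anova(m[, 1:2])
  ok <- stats::complete.cases(m[, 1:2])
  expect_equal(fit2$pairwise$p_adj,
               stats::t.test(m[ok, 1], m[ok, 2], paired = TRUE)$p.value,
               tolerance = 1e-10)

  # available-case mode uses every observed cell
  fit3 <- rm_anova(m, missing = "available")
  expect_equal(fit3$n_subjects, 6)
  expect_equal(fit3$df2, 17 - 1 - 5 - 2)   # N - 1 - (n-1) - (k-1)
  expect_error(rm_anova(m[, 1, drop = FALSE]), "2 conditions")
})

test_that("compare_collectives tests every parameter between two groups", {
  co <- sample_cohort(8, profiles = list(ugly = improv_preset("ugly"),
                                         beautiful = improv_preset("beautiful")),
                      seed = 5)
  mt <- metrics_table(co)
  res <- compare_collectives(mt, by = "task", variant = "pooled")
  expect_equal(nrow(res), length(improv:::metric_columns(mt)))
  expect_true(all(res$n1 + res$n2 <= 16))

  # constant parameter across groups -> t = 0
  mt$const_param <- 5
  attr(mt, "metric_cols") <- c(improv:::metric_columns(mt), "const_param")
  res2 <- compare_collectives(mt, by = "task", variant = "pooled")
  expect_equal(res2$t[res2$parameter == "const_param"], 0)

  # both variants report one row each
  res3 <- compare_collectives(mt, by = "task", variant = "both",
                              params = "pct_playing_time")
  expect_equal(sort(res3$variant), c("pooled", "welch"))
})

test_that("rejection rate of the collective comparison matches analytic power", {
  set.seed(14)
  n <- 30; delta <- 0.6
  oracle <- stats::power.t.test(n = n, delta = delta, sd = 1,
                                sig.level = 0.05)$power
  hits <- 0; reps <- 400
  for (r in seq_len(reps)) {
    tt <- two_sample_t(rnorm(n), rnorm(n, delta), variant = "pooled")
    if (tt$p < 0.05) hits <- hits + 1
  }
  expect_equal(hits / reps, oracle, tolerance = 0.06)
})
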