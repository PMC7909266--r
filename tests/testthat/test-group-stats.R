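# helper: construct values with an exact mean and sample SD
exact_sample <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

test_that("group summaries report n, mean and sample SD per group", {
  set.seed(5)
  d <- data.frame(
    group = rep(c("HC", "svPPA"), c(31, 19)),
    v = c(exact_sample(31, 28.5, 6.46), exact_sample(19, 13.0, 5.67)))
  s <- summarize_groups(d, "v")
  expect_equal(s$mean[s$group == "HC"], 28.5)
  expect_equal(s$sd[s$group == "HC"], 6.46)
  expect_identical(s$n[s$group == "svPPA"], 19L)
  # degenerate: repeated value has sd 0
  s0 <- summarize_groups(data.frame(group = "HC", v = rep(4, 5)), "v")
  expect_equal(s0$sd, 0)
  expect_error(summarize_groups(data.frame(group = "HC", v = 1), "v"),
               "fewer than 2")
  expect_error(summarize_groups(d, "nope"), "no such measure")
})

test_that("summary-statistic ANOVA reproduces the printed group effect", {
  rs <- reference_summaries("raw_cu", "original")
  a <- anova_from_summary(rs)
  expect_identical(a$df_between, 3L)
  expect_identical(a$df_within, 97L)
  expect_lt(abs(a$F - 36.2), 1.0)
  expect_lt(a$p, 0.001)
})

test_that("raw-data and summary-statistic ANOVA agree to numerical precision", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:20, k, replace = TRUE)
    g <- rep(letters[1:k], n)
    x <- stats::rnorm(sum(n), mean = rep(runif(k, 0, 10), n))
    a1 <- anova_oneway(x, g)
    a2 <- anova_from_summary(summarize_groups(data.frame(group = g, v = x), "v"))
    expect_lt(abs(a1$F - a2$F), 1e-10)
    expect_identical(c(a1$df_between, a1$df_within),
                     c(a2$df_between, a2$df_within))
    expect_lt(abs(a1$p - a2$p), 1e-10)
  }
})

test_that("ANOVA edge cases: equal means give F near 0, k = 2 gives F = t^2", {
  x <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b"), each = 6)
  a <- anova_oneway(c(x[1:6], x[1:6]), g)
  expect_equal(a$F, 0, tolerance = 1e-12)
  # all-constant input is defined as F = 0
  expect_equal(anova_oneway(rep(2, 8), rep(c("a", "b"), 4))$F, 0)
  set.seed(2)
  x2 <- stats::rnorm(12)
  tt <- stats::t.test(x2[1:6], x2[7:12], var.equal = TRUE)
  a2 <- anova_oneway(x2, g)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)
  s2 <- anova_from_summary(
    summarize_groups(data.frame(group = g, v = x2), "v"))
  expect_equal(s2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # identical summaries: F = 0
  same <- data.frame(n = c(10, 10), mean = c(5, 5), sd = c(2, 2))
  expect_equal(anova_from_summary(same)$F, 0)
})

test_that("Hedges' g reproduces the printed effect sizes from summaries", {
  # frozen oracle values computed directly from the corrected-g formula
  hc_cu <- list(n = 31, mean = 28.5, sd = 6.46)
  expect_equal(hedges_g(hc_cu, list(n = 25, mean = 20.3, sd = 6.07)),
               1.285537, tolerance = 1e-5)
  expect_equal(hedges_g(hc_cu, list(n = 19, mean = 13.0, sd = 5.67)),
               2.470454, tolerance = 1e-5)
  expect_equal(hedges_g(hc_cu, list(n = 26, mean = 14.5, sd = 5.81)),
               2.236860, tolerance = 1e-5)
  expect_equal(hedges_g(list(n = 31, mean = 20.9, sd = 5.67),
                        list(n = 25, mean = 23.1, sd = 9.45)),
               -0.2859536, tolerance = 1e-5)
})

test_that("Hedges' g is antisymmetric, zero for identical groups, and shrinks with SD", {
  a <- list(n = 12, mean = 10, sd = 2)
  b <- list(n = 15, mean = 7, sd = 3)
  expect_equal(hedges_g(a, b), -hedges_g(b, a))
  expect_equal(hedges_g(a, a), 0)
  a2 <- a; b2 <- b
  a2$sd <- a$sd * 2; b2$sd <- b$sd * 2
  expect_lt(abs(hedges_g(a2, b2)), abs(hedges_g(a, b)))
  # degenerate: zero pooled SD with unequal means
  expect_warning(
    g <- hedges_g(list(n = 5, mean = 1, sd = 0), list(n = 5, mean = 2, sd = 0)),
    "infinite")
  expect_identical(g, -Inf)
})

test_that("pairwise machinery: 6 comparisons for 4 groups at displayed alpha 0.008", {
  set.seed(14)
  g <- rep(c("HC", "svPPA", "lvPPA", "nfvPPA"), each = 10)
  x <- stats::rnorm(40)
  pw <- pairwise_ttests(x, g)
  expect_identical(attr(pw, "m"), 6L)
  expect_equal(attr(pw, "alpha_adjusted"), 0.05 / 6)
  expect_equal(attr(pw, "alpha_display"), 0.008)
  expect_identical(nrow(pw), 6L)
  # the reference group comes first in its pairs
  expect_true(all(pw$group2 != "HC"))
  # Bonferroni-significant pairs are a subset of unadjusted-significant pairs
  expect_true(all(pw$p[pw$significant] < 0.05))
  # identical groups are never significant
  same <- pairwise_ttests(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_gt(same$p[1], 0.99)
  expect_false(same$significant[1])
})

test_that("impairment flags use the one-sided HC normal range with a strict bound", {
  hc <- list(n = 31, mean = 20.9, sd = 5.67)
  lower <- 20.9 - 1.96 * 5.67
  expect_false(classify_impairment(hc, lower))        # exactly at the bound
  expect_false(classify_impairment(hc, hc$mean))      # at the control mean
  expect_true(classify_impairment(hc, lower - 1e-9))  # strictly below
  # high scores are never flagged (one-sided)
  expect_false(classify_impairment(hc, hc$mean + 10 * hc$sd))
  expect_identical(classify_impairment(hc, c(0, 21, 40)),
                   c(TRUE, FALSE, FALSE))
})
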