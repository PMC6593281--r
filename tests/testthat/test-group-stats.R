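# Statistical battery: Welch t (raw and from summaries), Mann-Whitney,
# chi-square, covariate-adjusted comparison, Bonferroni, partial correlation.

test_that("welch_t on raw data equals welch_t_from_summary to 1e-12", {
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    raw <- welch_t(a, b)
    summ <- welch_t_from_summary(mean(a), sd(a) / sqrt(length(a)), length(a),
                                 mean(b), sd(b) / sqrt(length(b)), length(b))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$df, summ$df, tolerance = 1e-12)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
    # and both agree with stats::t.test(var.equal = FALSE)
    ref <- stats::t.test(a, b)
    expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(raw$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("test statistics are invariant to unit rescaling", {
  set.seed(2)
  a <- rnorm(20, 5); b <- rnorm(25, 6)
  k <- 37.2
  expect_equal(welch_t(a, b)$statistic, welch_t(k * a, k * b)$statistic,
               tolerance = 1e-12)
  expect_equal(mann_whitney(a, b)$statistic,
               mann_whitney(k * a, k * b)$statistic)
  cov <- data.frame(x = rnorm(45))
  grp <- rep(c("control", "patient"), c(20, 25))
  expect_equal(adjusted_group_compare(c(a, b), grp, cov)$statistic,
               adjusted_group_compare(k * c(a, b), grp, cov)$statistic,
               tolerance = 1e-10)
  pc1 <- partial_correlation(a, b[1:20], data.frame(z = rnorm(20)))
  set.seed(3); z <- data.frame(z = rnorm(20))
  expect_equal(partial_correlation(a, b[1:20], z)$r,
               partial_correlation(k * a, k * b[1:20], z)$r,
               tolerance = 1e-12)
})

test_that("welch_t type-I error is nominal (1000 reps)", {
  set.seed(4)
  rej <- mean(vapply(1:1000, function(i)
    welch_t(rnorm(30), rnorm(30))$p_value < 0.05, logical(1)))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("mann_whitney switches between exact and normal approximations", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.4, 6.3, 7.7, 8.1, 9.0)
  res <- mann_whitney(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$method, "mann_whitney_exact")
  # ties or larger groups fall back to the corrected normal approximation
  res_t <- mann_whitney(c(a, a), c(b, b))
  ref_t <- suppressWarnings(stats::wilcox.test(c(a, a), c(b, b),
                                               exact = FALSE, correct = TRUE))
  expect_equal(res_t$p_value, ref_t$p.value)
  expect_equal(res_t$method, "mann_whitney_normal")
})

test_that("chi_square_counts is the Pearson test without correction", {
  tab <- matrix(c(18, 12, 10, 20), 2, 2, byrow = TRUE)
  res <- chi_square_counts(tab)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, 1)
  expect_equal(res$p_value, ref$p.value)
  res_y <- chi_square_counts(tab, correct = TRUE)
  expect_equal(res_y$p_value, stats::chisq.test(tab)$p.value)
  expect_error(chi_square_counts(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("adjusted_group_compare reduces to the pooled t-test without covariates", {
  set.seed(5)
  y <- c(rnorm(15, 0), rnorm(15, 1))
  grp <- rep(c("control", "patient"), each = 15)
  res <- adjusted_group_compare(y, grp)
  ref <- stats::t.test(y[16:30], y[1:15], var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_gt(res$statistic, 0)     # patient minus control direction
})

test_that("adjusted_group_compare removes covariate confounding", {
  set.seed(6)
  n <- 60
  covar <- data.frame(age = rnorm(n, 50, 6))
  grp <- rep(c("control", "patient"), each = n / 2)
  y <- 2 * covar$age + rnorm(n)          # no true group effect
  rej <- mean(vapply(1:500, function(i) {
    yy <- 2 * covar$age + rnorm(n)
    adjusted_group_compare(yy, grp, covar)$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.035)
  expect_error(adjusted_group_compare(y, rep("a", n)), "two levels")
  expect_error(adjusted_group_compare(y, grp,
                                      data.frame(z = covar$age, w = covar$age)),
               "rank-deficient")
})

test_that("bonferroni implements p <= alpha/m with adjusted p = min(1, m p)", {
  one <- bonferroni(0.04, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$p_adjusted, 0.04)
  res <- bonferroni(c(0.01, 0.2, 0.002, 0.6, 0.011), alpha = 0.05)
  expect_equal(res$p_adjusted, pmin(1, 5 * res$p_value))
  expect_equal(res$reject, res$p_value <= 0.01)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(bonferroni(c(0.01, rep(0.5, 4)))$reject[1])  # 0.01 * 5 = 0.05 rejects
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial_correlation equals correlation of covariate residuals", {
  set.seed(7)
  n <- 40
  z <- data.frame(a = rnorm(n), b = rnorm(n))
  x <- 0.5 * z$a + rnorm(n)
  y <- -0.3 * z$a + 0.4 * x + rnorm(n)
  pc <- partial_correlation(x, y, z)
  rx <- residuals(lm(x ~ a + b, data = z))
  ry <- residuals(lm(y ~ a + b, data = z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 2L - 2L)
  ref_t <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(-abs(ref_t), pc$df), tolerance = 1e-12)
  # no covariates -> plain Pearson with n - 2 df
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_error(partial_correlation(x[1:4], y[1:4], z[1:4, ]), "n >")
})
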