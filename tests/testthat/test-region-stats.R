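test_that("wilcoxon V matches hand-ranked examples", {
  y <- rep(0, 3)
  r1 <- wilcoxon_paired(c(1, 2, 3), y) # all positive: V = n(n+1)/2
  expect_equal(r1$statistic, 6)
  r2 <- wilcoxon_paired(c(1, -2, 3), y) # ranks 1,2,3; positives 1 and 3
  expect_equal(r2$statistic, 4)
  expect_error(wilcoxon_paired(1:5, 1:5), "zero")
})

test_that("wilcoxon V is complementary between orientations", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    v_xy <- wilcoxon_paired(x, y)$statistic
    v_yx <- wilcoxon_paired(y, x)$statistic
    expect_equal(v_xy + v_yx, n * (n + 1) / 2)
  }
})

test_that("wilcoxon agrees with the sign-flip enumeration oracle", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- wilcoxon_paired(x, y)
    expect_equal(res$statistic, oracle_wilcoxon_v(x, y))
    expect_equal(res$p_value, oracle_wilcoxon_p_exact(x, y))
  }
  # tied data take the corrected normal approximation
  x <- c(1, 2, 2, 3, 5, 5, 7, 9)
  y <- c(0, 4, 1, 1, 2, 8, 3, 2)
  res <- wilcoxon_paired(x, y)
  expect_match(res$method, "normal")
  expect_equal(res$p_value, oracle_wilcoxon_p_normal(x, y))
})

test_that("chi-square goodness of fit matches closed forms", {
  r0 <- chisq_equal(c(10, 10, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- chisq_equal(c(17, 4, 7))
  expect_equal(r1$statistic, 9.928571, tolerance = 1e-6)
  expect_equal(r1$df, 2)
  # two categories (n, 0): statistic equals n
  for (n in c(4, 9, 25)) {
    expect_equal(chisq_equal(c(n, 0))$statistic, n)
  }
  expect_error(chisq_equal(c(0, 0)), "zero")
})

test_that("binomial detection-count test matches closed forms", {
  expect_equal(binomial_detected(5, 5)$p_value, 1)
  expect_equal(binomial_detected(8, 0)$p_value, 2 * 0.5^8)
  # the published detected counts: report computed exact p
  r <- binomial_detected(86, 53)
  expect_equal(r$p_value, oracle_binom_p(86, 139))
  expect_error(binomial_detected(0, 0), "zero")
})

test_that("dunn_sidak reproduces stated critical levels and bounds", {
  expect_equal(dunn_sidak(0.05, 1), 0.05)
  expect_equal(dunn_sidak(0.05, 3), 0.0169, tolerance = 1e-4 / 0.0169)
  expect_equal(dunn_sidak(0.05, 6), 0.00851, tolerance = 1e-5 / 0.00851)
  # strictly decreasing in m; close to Bonferroni from below
  ms <- 1:12
  vals <- dunn_sidak(0.05, ms)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 0.05 / ms + 0.05^2))
  expect_true(all(vals > 0.05 / ms - 1e-12))
  expect_error(dunn_sidak(0.05, 0), "m")
  expect_error(dunn_sidak(1.5, 2), "alpha")
})

test_that("paired t matches hand formula and rejects degenerate input", {
  r <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  o <- oracle_paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$p_value, o$p)
  expect_error(paired_t(1, 2), "two pairs")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero variance")
})

test_that("perfect correlations give degenerate bootstrap intervals", {
  a <- c(0, 20, 40, 60, 80, 100)
  r1 <- bootstrap_correlation(a, a, reps = 200, seed = 1)
  expect_equal(r1$estimate, 1)
  expect_equal(c(r1$lower, r1$upper), c(1, 1))
  # two-level design 0/100 swaps exactly: r = -1 after transform
  a2 <- c(0, 100, 0, 100, 0, 100)
  r2 <- bootstrap_correlation(a2, 100 - a2, reps = 200, seed = 1)
  expect_equal(r2$estimate, -1)
  expect_equal(c(r2$lower, r2$upper), c(-1, -1))
  expect_error(
    bootstrap_correlation(rep(50, 5), c(1, 2, 3, 4, 5)),
    "zero variance"
  )
  expect_error(bootstrap_correlation(c(-5, 1, 2), c(1, 2, 3)), "\\[0, 100\\]")
})

test_that("bootstrap CI is seed-reproducible and monotone in confidence", {
  set.seed(30)
  a <- runif(40, 0, 100)
  b <- pmin(100, pmax(0, a + rnorm(40, sd = 25)))
  r1 <- bootstrap_correlation(a, b, reps = 500, seed = 9)
  r2 <- bootstrap_correlation(a, b, reps = 500, seed = 9)
  expect_identical(r1, r2)
  r90 <- bootstrap_correlation(a, b, reps = 500, seed = 9, conf = 0.90)
  expect_gte(r90$lower, r1$lower)
  expect_lte(r90$upper, r1$upper)
  expect_true(r1$lower <= r1$estimate && r1$estimate <= r1$upper)
})

test_that("bootstrap CI covers zero for independent columns", {
  covered <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    a <- runif(86, 0, 100)
    b <- runif(86, 0, 100)
    ci <- bootstrap_correlation(a, b, reps = 1000, seed = s)
    ci$lower <= 0 && ci$upper >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
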