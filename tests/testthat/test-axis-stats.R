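sub_prof <- function(...) {
  m <- rbind(...)
  data.frame(
    gene = sprintf("g%d", seq_len(nrow(m))),
    CA1 = m[, 1], CA2 = m[, 2], CA3 = m[, 3], DG = m[, 4]
  )
}

test_that("delta follows its defining arithmetic", {
  d <- compute_delta(sub_prof(
    c(10, 10, 10, 10), # DG = meanCA -> 0
    c(9, 9, 9, 99), # log10(100) - log10(10) = 1 at offset 1
    c(30, 60, 90, 120)
  ), offset = 1)
  expect_equal(d$delta[1], 0)
  expect_equal(d$delta[2], 1)
  expect_equal(d$mean_ca[3], 60)
  # zero everywhere at offset 2 -> 0
  d2 <- compute_delta(sub_prof(c(0, 0, 0, 0)), offset = 2)
  expect_equal(d2$delta, 0)
  expect_error(compute_delta(sub_prof(c(1, 1, 1, 1)), offset = 3), "offset")
  expect_error(
    compute_delta(data.frame(gene = "g", CA1 = 1, CA2 = 1, DG = 1)),
    "CA3"
  )
})

test_that("delta is antisymmetric under swapping DG with the CA mean", {
  set.seed(3)
  v <- matrix(runif(40, 0, 100), ncol = 4)
  p <- sub_prof(v)
  swapped <- p
  mean_ca <- rowMeans(p[, c("CA1", "CA2", "CA3")])
  swapped$DG <- mean_ca
  swapped$CA1 <- swapped$CA2 <- swapped$CA3 <- p$DG
  expect_equal(
    compute_delta(p)$delta,
    -compute_delta(swapped)$delta
  )
})

test_that("genes with missing subfields are excluded and counted", {
  p <- sub_prof(c(1, 2, 3, 4), c(5, 6, 7, 8))
  p$DG[2] <- NA
  expect_message(d <- compute_delta(p), "1 gene")
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "n_excluded"), 1)
})

test_that("welch test matches the hand formula", {
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  o <- oracle_welch(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, o$t)
  expect_equal(r$p_value, o$p)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("permutation test enumerates small designs exactly", {
  d_eq <- make_delta(rep(2, 8), rep(c("A", "B"), each = 4))
  expect_equal(permutation_test(d_eq)$p_value, 1)

  d <- make_delta(c(1, 2, 10, 11), c("A", "A", "B", "B"))
  r <- permutation_test(d)
  expect_equal(r$method, "exhaustive")
  expect_equal(r$observed, -9)
  expect_equal(r$p_value, 2 / 6)

  expect_error(
    permutation_test(make_delta(1:3, c("A", "A", "A"))),
    "non-empty"
  )
})

test_that("monte-carlo permutation p converges to the exhaustive p", {
  set.seed(40)
  fixtures <- list(
    list(n_a = 3, n_b = 3), list(n_a = 4, n_b = 4),
    list(n_a = 5, n_b = 5), list(n_a = 6, n_b = 6),
    list(n_a = 4, n_b = 8), list(n_a = 2, n_b = 10)
  )
  for (fx in fixtures) {
    v <- rnorm(fx$n_a + fx$n_b, mean = rep(c(1, 0), c(fx$n_a, fx$n_b)))
    d <- make_delta(v, rep(c("A", "B"), c(fx$n_a, fx$n_b)))
    p_ex <- permutation_test(d)$p_value
    p_mc <- permutation_test(d, reps = 10000, seed = 5, exhaustive_max = 0)$p_value
    expect_lt(abs(p_mc - p_ex), 0.01)
  }
})

test_that("permutation test is seed-reproducible on the monte-carlo path", {
  d <- make_delta(rnorm(30), rep(c("A", "B"), 15))
  r1 <- permutation_test(d, reps = 500, seed = 7)
  r2 <- permutation_test(d, reps = 500, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$method, "monte carlo")
})

test_that("fold difference follows its definition and is base-invariant", {
  d_eq <- make_delta(rep(1, 6), rep(c("A", "B"), 3))
  expect_equal(fold_difference(d_eq), 1)
  d1 <- make_delta(c(1.5, 1.5, 0.5, 0.5), c("A", "A", "B", "B"))
  expect_equal(fold_difference(d1), 10)
  expect_equal(enrichment_fold(d1), sqrt(10))

  # computing delta in base e and exponentiating in base e gives the same fold
  p <- sub_prof(c(9, 9, 9, 99), c(99, 99, 99, 9))
  gr <- data.frame(gene = c("g1", "g2"), group = c("A", "B"))
  f10 <- fold_difference(compute_delta(p, gr, log_base = 10))
  fe <- fold_difference(
    compute_delta(p, gr, log_base = exp(1)),
    log_base = exp(1)
  )
  expect_equal(f10, fe)
})

test_that("FPKM axis floors sub-threshold values and keeps the boundary", {
  fp <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    CA1 = c(3.9, 4, 50, 10), CA2 = c(1, 4, 50, 10),
    CA3 = c(0, 4, 50, 10), DG = c(100, 40, 5, 9)
  )
  gr <- data.frame(gene = fp$gene, group = c("A", "A", "B", "B"))
  res <- fpkm_axis(fp, gr, reps = 100, seed = 1)
  # g1 CA values are all below 4 -> zeroed -> delta = log10(101/1)
  expect_equal(res$delta$delta[1], log10(101))
  # g2 CA values exactly 4 are retained
  expect_equal(res$delta$mean_ca[2], 4)
  expect_error(fpkm_axis(fp[, -2], gr), "CA1")
  fp_bad <- fp
  fp_bad$DG[1] <- -1
  expect_error(fpkm_axis(fp_bad, gr), "non-negative")
})

test_that("FPKM axis agrees in sign with the intensity axis on synthetic truth", {
  g <- generate_profiles(synthetic_config(seed = 12))
  groups <- g$truth[g$truth$group %in% c("A", "B"), c("gene", "group")]
  norm_sub <- normalize_profiles(g$profiles, regions = HPC_SUBFIELDS)
  d_int <- compute_delta(norm_sub, groups)
  fp <- generate_fpkm(g$truth, seed = 13)
  res <- fpkm_axis(fp, groups, reps = 2000, seed = 14)
  gi <- sign(
    mean(d_int$delta[d_int$group %in% "A"]) -
      mean(d_int$delta[d_int$group %in% "B"])
  )
  expect_equal(gi, sign(res$permutation$observed))
  expect_lt(res$permutation$p_value, 0.01)
})
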