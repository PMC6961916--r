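prof3 <- function(...) {
  m <- rbind(...)
  data.frame(
    gene = sprintf("g%d", seq_len(nrow(m))),
    HPC = m[, 1], CX = m[, 2], CB = m[, 3]
  )
}

test_that("normalization divides by the per-gene maximum", {
  p <- prof3(c(10, 20, 40), c(0, 0, 0), c(5, 5, 5))
  n <- normalize_profiles(p)
  expect_equal(unlist(n[1, BRAIN_REGIONS]), c(HPC = 25, CX = 50, CB = 100))
  expect_equal(unlist(n[2, BRAIN_REGIONS]), c(HPC = 0, CX = 0, CB = 0))
  expect_equal(unlist(n[3, BRAIN_REGIONS]), c(HPC = 100, CX = 100, CB = 100))
  expect_equal(attr(n, "not_expressed"), "g2")
  expect_error(normalize_profiles(prof3(c(-1, 0, 0))), "non-negative")
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(1)
  p <- prof3(
    c(3, 150, 88), c(0, 12, 255), c(77, 77, 10), c(1, 2, 3)
  )
  n1 <- normalize_profiles(p)
  n2 <- normalize_profiles(as.data.frame(n1))
  expect_equal(as.data.frame(n1), as.data.frame(n2))
  # any positive per-gene rescaling is removed
  p_scaled <- p
  p_scaled[, BRAIN_REGIONS] <- p[, BRAIN_REGIONS] * c(0.3, 2, 1.7, 0.01)
  expect_equal(
    as.data.frame(normalize_profiles(p_scaled)),
    as.data.frame(n1)
  )
  # every expressed gene attains exactly 100
  expect_true(all(apply(n1[, BRAIN_REGIONS], 1, max) == 100))
})

test_that("detection calls honour threshold (inclusive) and punctate rule", {
  p <- prof3(c(0, 10, 9.99), c(15, 15, 15))
  cv <- prof3(c(0, 0, 0), c(1, 5, 1))
  calls <- call_detection(p, threshold = 10, punctate_cv = 3, pixel_cv = cv)
  get <- function(g, rg) calls[calls$gene == g & calls$region == rg, ]
  expect_equal(get("g1", "HPC")$status, "absent")
  expect_equal(get("g1", "HPC")$reason, "below-threshold")
  expect_equal(get("g1", "CX")$status, "expressed") # boundary inclusive
  expect_equal(get("g1", "CB")$status, "absent")
  # mean above threshold but high pixel CV -> punctate -> absent
  expect_equal(get("g2", "CX")$status, "absent")
  expect_equal(get("g2", "CX")$reason, "punctate")
  expect_equal(get("g2", "HPC")$status, "expressed")
})

test_that("punctate fixture: few bright pixels fail the CV rule", {
  # 1% of pixels at 255, rest 0: mean 2.55, CV = sd/mean ~ 9.9
  px <- c(rep(255, 10), rep(0, 990))
  cv <- sd(px) / mean(px)
  expect_gt(cv, 3)
  p <- data.frame(gene = "g1", HPC = mean(px), CX = 50, CB = 0)
  cvt <- data.frame(gene = "g1", HPC = cv, CX = 0.5, CB = 0)
  calls <- call_detection(p,
    threshold = 2, punctate_cv = 3, pixel_cv = cvt
  )
  expect_equal(calls$status[calls$region == "HPC"], "absent")
  expect_equal(calls$reason[calls$region == "HPC"], "punctate")
})

test_that("prominence classification follows the exclusive/tie rules", {
  p <- prof3(
    c(50, 0, 0), # exclusive HPC
    c(100, 50, 50), # prominent HPC
    c(100, 100, 0), # tie -> shared
    c(0, 0, 0) # absent
  )
  n <- normalize_profiles(p)
  calls <- call_detection(p, threshold = 10)
  cat_tab <- classify_prominence(calls, n)
  expect_equal(cat_tab$category, c("exclusive", "prominent", "shared", "absent"))
  expect_equal(cat_tab$region, c("HPC", "HPC", NA, NA))
  # categories partition the panel
  expect_equal(nrow(cat_tab), nrow(p))
})

test_that("classification from incomplete regions warns", {
  p <- prof3(c(50, 20, 0))
  n <- normalize_profiles(p)
  calls <- call_detection(p, threshold = 10)
  calls <- calls[calls$region != "CB", ]
  expect_warning(
    classify_prominence(calls, n),
    "available regions"
  )
})

test_that("summary counts use the stated denominators", {
  # 86 of 253 detected in HPC -> 34.0%; 17 exclusive of 98 brain -> 17.3%
  n_genes <- 253
  cats <- data.frame(
    gene = sprintf("g%03d", 1:n_genes),
    category = c(
      rep("exclusive", 17), rep("prominent", 69),
      rep("shared", 12), rep("absent", 155)
    ),
    region = c(rep("HPC", 17), rep("HPC", 69), rep(NA, 12), rep(NA, 155))
  )
  calls <- data.frame(
    gene = rep(cats$gene, 3),
    region = rep(BRAIN_REGIONS, each = n_genes),
    status = c(
      rep("expressed", 86), rep("absent", 167), # HPC
      rep("expressed", 76), rep("absent", 177), # CX
      rep("expressed", 53), rep("absent", 200) # CB
    )
  )
  counts <- tabulate_counts(calls, cats)
  hpc <- counts[counts$region == "HPC", ]
  expect_equal(hpc$detected_n, 86)
  expect_equal(hpc$detected_pct, 34.0)
  expect_equal(hpc$exclusive_n, 17)
  expect_equal(hpc$exclusive_pct, 17.3)
  expect_equal(attr(counts, "n_brain_expressed"), 98)
  expect_equal(counts$detected_pct[counts$region == "CX"], 30.0)

  # empty input -> zero counts
  empty <- tabulate_counts(calls[0, ], cats[0, ], n_total = 0)
  expect_true(all(empty$detected_n == 0))
})
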