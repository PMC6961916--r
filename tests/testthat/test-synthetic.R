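test_that("generator is deterministic and respects zero-noise arithmetic", {
  cfg <- synthetic_config(noise_sd = 0, dg_fold_A = 8.33, subfield_base = 24, seed = 11)
  g1 <- generate_profiles(cfg)
  g2 <- generate_profiles(cfg)
  expect_identical(g1, g2)

  a_genes <- g1$truth$gene[g1$truth$group == "A"]
  expect_equal(
    g1$truth$true_DG[g1$truth$group == "A"],
    rep(24 * 8.33, length(a_genes))
  )
  # zero noise: observed equals truth
  expect_equal(
    g1$profiles$DG[match(a_genes, g1$profiles$gene)],
    rep(199.92, length(a_genes))
  )
  b <- g1$truth$group == "B"
  expect_true(all(g1$truth$true_CA1[b] > g1$truth$true_DG[b]))
})

test_that("different seeds give different tables, same seed identical bytes", {
  cfg1 <- synthetic_config(seed = 1)
  cfg2 <- synthetic_config(seed = 2)
  p1 <- generate_profiles(cfg1)$profiles
  p2 <- generate_profiles(cfg2)$profiles
  expect_false(identical(p1, p2))
})

test_that("observed intensities are clipped to [0, 255] and FPKM non-negative", {
  cfg <- synthetic_config(noise_sd = 60, seed = 3) # extreme noise to hit bounds
  g <- generate_profiles(cfg)
  m <- as.matrix(g$profiles[, ALL_REGIONS])
  expect_true(all(m >= 0 & m <= 255))
  fp <- generate_fpkm(g$truth, seed = 4)
  expect_true(all(as.matrix(fp[, HPC_SUBFIELDS]) >= 0))
  expect_equal(nrow(g$truth), cfg$n_genes)
})

test_that("study-condition counts are realized at defaults", {
  g <- generate_profiles(synthetic_config(seed = 5))
  expect_equal(sum(g$truth$det_HPC), 86)
  expect_equal(sum(g$truth$det_HPC | g$truth$det_CX | g$truth$det_CB), 98)
  expect_equal(table(g$truth$group)[["A"]], 16)
  expect_equal(table(g$truth$group)[["B"]], 16)
})

test_that("configuration validation rejects invalid folds and proportions", {
  expect_error(synthetic_config(dg_fold_A = 0), "fold")
  expect_error(synthetic_config(frac_brain_expressed = 1.2), "proportion")
  expect_error(synthetic_config(n_informative = 300), "n_informative")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("realized group A DG/CA ratio stays within 15% of configured fold", {
  ratios <- vapply(1:20, function(s) {
    g <- generate_profiles(synthetic_config(seed = s))
    a <- g$truth$group == "A"
    pr <- g$profiles[match(g$truth$gene[a], g$profiles$gene), ]
    mean(pr$DG / rowMeans(pr[, c("CA1", "CA2", "CA3")]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 8.33) / 8.33, 0.15)
})

test_that("FPKM coupling is monotone, floored at silence, rank-concordant", {
  g <- generate_profiles(synthetic_config(seed = 6))
  # intercept 0, zero noise, zero truth -> FPKM exactly 1 (< 4, undetected)
  silent <- g$truth[!(g$truth$det_HPC | g$truth$det_CX | g$truth$det_CB), ][1, , drop = FALSE]
  fp0 <- generate_fpkm(silent, slope = 1.2, intercept = 0, log_noise_sd = 0, seed = 1)
  expect_equal(unlist(fp0[1, HPC_SUBFIELDS]), c(CA1 = 1, CA2 = 1, CA3 = 1, DG = 1))

  # zero noise: FPKM rank order equals true-intensity rank order
  fp <- generate_fpkm(g$truth, log_noise_sd = 0, seed = 1)
  expect_equal(rank(fp$DG), rank(g$truth$true_DG))

  # defaults: Spearman correlation > 0.8 across expressed genes
  fp2 <- generate_fpkm(g$truth, seed = 2)
  expr <- g$truth$true_DG > 0
  expect_gt(
    cor(g$truth$true_DG[expr], fp2$DG[expr], method = "spearman"), 0.8
  )
  expect_error(generate_fpkm(g$truth, slope = 0), "slope")
})

test_that("effect codes follow group with the configured concordance", {
  g <- generate_profiles(synthetic_config(seed = 8))
  eff1 <- generate_effects(g$truth, concordance = 1, seed = 1)
  expect_true(all(eff1$ltp[eff1$group %in% "A"] == -1))
  expect_true(all(eff1$neurogenesis[eff1$group %in% "B"] == 1))
  expect_true(all(is.na(eff1$ltp[is.na(eff1$group)])))

  # concordance 0.5: mean code indistinguishable from 0 across seeds
  codes_a <- unlist(lapply(1:30, function(s) {
    e <- generate_effects(g$truth, concordance = 0.5, seed = s)
    e$ltp[e$group %in% "A"]
  }))
  expect_lt(abs(mean(codes_a)), 3 / sqrt(length(codes_a)) + 0.05)
  expect_error(generate_effects(g$truth, concordance = 1.5), "concordance")
})

test_that("rendering encodes the stated anchor colors", {
  lay <- atlas_layout()
  img0 <- render_image(c(DG = 0), lay)
  dg_px <- lay$mask == lay$vocab[["DG"]]
  expect_true(all(img0[, , 1][dg_px] == 0) && all(img0[, , 3][dg_px] == 0))
  img85 <- render_image(c(DG = 85), lay)
  expect_true(all(img85[, , 1][dg_px] == 1))
  expect_true(all(img85[, , 2][dg_px] == 0) && all(img85[, , 3][dg_px] == 0))
  expect_error(render_image(c(NOPE = 10), lay), "absent from layout")
})
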