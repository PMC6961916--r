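#!/usr/bin/env Rscript
# Stage 4: the challenge/sufficiency axis within the hippocampus — subfield
# correlations, per-gene DG-vs-CA log ratios for the informative genes,
# Welch's t, the two-stage permutation test, the fold-difference summary,
# offset stability, and the FPKM (RNA-seq) cross-validation.

suppressPackageStartupMessages(library(hippaxis))

seed <- as.integer(Sys.getenv("HIPPAXIS_SEED", "1"))
out <- "results/axis"

cfg <- pipeline_config(
  mode = "tables",
  intensity_path = "results/synthetic/intensity.tsv",
  groups_path = "results/synthetic/groups.tsv",
  fpkm_path = "results/synthetic/fpkm.tsv",
  seed = seed
)
res <- run_pipeline(cfg, out, quiet = TRUE)

ax <- res$axis
message(sprintf(
  "Welch t = %.2f (df = %.2f, p = %.2g); permutation p = %.2g (%d reps)",
  ax$welch$statistic, ax$welch$df, ax$welch$p_value,
  ax$permutation$p_value, ax$permutation$reps
))
message(sprintf(
  "fold difference (A vs B) = %.2f; per-group enrichment fold = %.2f",
  ax$fold_difference, ax$enrichment_fold
))
message(sprintf(
  "offset %d vs %d: permutation p %.2g vs %.2g (same conclusion: %s)",
  cfg$offset, ax$other_offset$offset, ax$permutation$p_value,
  ax$other_offset$permutation$p_value,
  identical(
    ax$permutation$p_value < 0.05,
    ax$other_offset$permutation$p_value < 0.05
  )
))
message(sprintf(
  "FPKM cross-validation: permutation p = %.2g (floor %g FPKM)",
  res$fpkm$permutation$p_value, cfg$fpkm_floor
))

# per-gene delta bar chart (informative genes, ordered by delta)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  d <- res$delta[res$delta$group %in% c("A", "B"), ]
  d <- d[order(d$delta, decreasing = TRUE), ]
  d$gene <- factor(d$gene, levels = d$gene)
  p <- ggplot2::ggplot(d, ggplot2::aes(gene, delta, fill = group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      y = expression(Delta == log[10](DG + 1) - log[10](CA + 1)),
      x = NULL, fill = "group"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out, "delta_by_gene.pdf"), p,
    width = 5, height = 6
  )
  message("wrote ", file.path(out, "delta_by_gene.pdf"))
}
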