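#!/usr/bin/env Rscript
# Stage 5: ligand-effect comparison — do challenge (A) and sufficiency (B)
# receptor groups differ in their coded effects on long-term potentiation
# and on neurogenesis?

suppressPackageStartupMessages(library(hippaxis))

effects <- read_gene_table("results/synthetic/effects.tsv")
out <- "results/function"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (par in c("ltp", "neurogenesis")) {
  m <- group_mean_scores(effects, par)
  tests <- compare_groups(effects, par)
  message(sprintf(
    "%s: mean code A = %.2f (n=%d), B = %.2f (n=%d); t p = %.2g, chi-square p = %.2g",
    par, m$mean_code[1], m$n[1], m$mean_code[2], m$n[2],
    tests$t$p_value, tests$chisq$p_value
  ))
  rows[[par]] <- data.frame(
    parameter = par,
    mean_A = m$mean_code[1], n_A = m$n[1],
    mean_B = m$mean_code[2], n_B = m$n[2],
    t_p = tests$t$p_value, chisq_p = tests$chisq$p_value
  )
}
write_gene_table(do.call(rbind, rows), file.path(out, "effect_summary.tsv"))
message("summary written to ", out)
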