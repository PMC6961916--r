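#!/usr/bin/env Rscript
# Stage 1: generate the synthetic expression atlas under the default study
# conditions (253 genes; 98 brain-expressed, 86 in HPC; 32 informative genes
# split 16 challenge / 16 sufficiency with an 8.33-fold DG-vs-CA contrast)
# and write the tables plus a handful of rendered pseudocolor images.

suppressPackageStartupMessages(library(hippaxis))

seed <- as.integer(Sys.getenv("HIPPAXIS_SEED", "1"))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
gen <- generate_profiles(cfg)
write_gene_table(gen$profiles, file.path(out, "intensity.tsv"))
write_gene_table(gen$truth, file.path(out, "truth.tsv"))

fpkm <- generate_fpkm(gen$truth, seed = substream_seed(seed, "fpkm"))
write_gene_table(fpkm, file.path(out, "fpkm.tsv"))

effects <- generate_effects(gen$truth,
  concordance = cfg$effect_concordance,
  seed = substream_seed(seed, "effects")
)
write_gene_table(effects, file.path(out, "effects.tsv"))
write_gene_table(
  gen$truth[gen$truth$group %in% c("A", "B"), c("gene", "group")],
  file.path(out, "groups.tsv")
)

# render a small image fixture: all informative genes plus a few silent ones
render_genes <- c(
  gen$truth$gene[gen$truth$group %in% c("A", "B")],
  head(gen$truth$gene[!gen$truth$det_HPC & !gen$truth$det_CX &
    !gen$truth$det_CB], 3)
)
write_atlas_images(gen$profiles, file.path(out, "images"),
  noise_sd = 0, seed = seed, genes = render_genes
)

message(
  "wrote ", length(render_genes), " rendered images and tables for ",
  cfg$n_genes, " genes to ", out,
  " (", sum(gen$truth$det_HPC), " HPC-expressed, ",
  sum(gen$truth$group == "A"), "+", sum(gen$truth$group == "B"),
  " informative)"
)
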