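# hippaxis

Quantification of endocrine receptor expression across mouse brain regions
and statistical analysis of the hippocampal "challenge/sufficiency" axis.

## What it is for

In situ hybridization atlases publish gene expression as pseudocolored
sections (black → red → yellow → white encoding a 0–255 intensity).
`hippaxis` turns such images — or pre-quantified intensity tables — into a
reproducible analysis of where endocrine receptors are expressed in the
brain and how they are organized within the hippocampus:

- **Image quantification**: inversion of the pseudocolor lookup table and
  region-of-interest mean intensities, with an optional two-rater protocol
  that flags discordant measurements.
- **Normalization and classification**: per-gene percent-of-maximum
  profiles; detection, exclusivity and prominence calls across hippocampus
  (HPC), cortex (CX) and cerebellum (CB).
- **Cross-region statistics**: paired Wilcoxon signed-rank tests, exact
  binomial tests on detected counts, chi-square goodness-of-fit tests,
  case-bootstrap correlations of arcsine-square-root transformed values,
  and Dunn–Šidák corrected critical levels.
- **The DG–CA axis**: per-gene log ratios
  `Δ = log10(DG + c) − log10(meanCA + c)` (c ∈ {1, 2}), Welch's t between
  the challenge (A) and sufficiency (B) receptor groups, a two-stage
  permutation test (10 000 label randomizations, exhaustive enumeration for
  small panels), fold-difference summaries, and an RNA-seq (FPKM)
  cross-validation with a 4-FPKM detection floor.
- **Ligand-effect comparison**: group differences in coded effects on
  long-term potentiation and neurogenesis (Student's t and 2×2 chi-square).
- **A synthetic atlas generator** with known ground truth (253 genes, 32
  informative split 16/16, configurable DG/CA fold and noise) for
  end-to-end validation, including rendered pseudocolor PNG fixtures.

It is aimed at computational neuroscientists who want the full analysis
reproducible from either atlas screenshots or transcribed intensity tables.

## Worked example

```r
library(hippaxis)

cfg <- pipeline_config(
  mode = "synthetic", seed = 1,
  synthetic = synthetic_config(seed = 1)   # defaults: 253 genes, fold 8.33
)
res <- run_pipeline(cfg, "run1", quiet = TRUE)

res$counts[res$counts$region == "HPC", c("detected_pct", "prominent_pct")]
#>   detected_pct prominent_pct
#> 1         34.4          62.2

res$region_tests$wilcoxon_HPC_vs_CX
#> Wilcoxon signed rank (normal approximation)
#>   V = 3655, p = 1.251e-06 (two.sided, n = 96)

res$axis$welch
#> Welch two-sample t
#>   t = 73.7651, df = 21.18, p = 4.977e-27 (two.sided, n = 32)

res$axis$permutation
#> permutation test (monte carlo, 10000 assignments): observed diff = 1.836, p = 9.999e-05

res$axis$enrichment_fold
#> [1] 8.275633
```

Reading the output: about a third of the panel is detectably expressed in
the hippocampus and the hippocampus is the most prominent site for ~62% of
brain-expressed genes; raw expression is significantly higher in HPC than
CX (Wilcoxon V); and the challenge-group genes are DG-enriched relative to
the sufficiency group (positive observed difference), with a per-group
enrichment fold recovering the configured 8.33 and a permutation p at the
resolution floor of 10 000 replicates.

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulate → quantify images → brain regions → subfield axis →
receptor function), writing tables under `results/`.

To analyze real data instead, supply `mode = "tables"` with an intensity
TSV (`gene, HPC, CX, CB, CA1, CA2, CA3, DG`), optional group labels, FPKM
and effect tables — `inst/extdata/README.md` documents the dialect — or
`mode = "images"` with a directory of PNGs plus a mask and vocabulary.

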