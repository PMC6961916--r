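---
title: "Quantifying regional endocrine receptor expression and the DG-CA challenge-sufficiency axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional endocrine receptor expression and the DG-CA challenge-sufficiency axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippaxis)
```

## The problem

In situ hybridization atlases report gene expression as pseudocolored
sagittal sections: a black → red → yellow → white color ramp encoding a
0–255 intensity. Densitometry of such images — place a region of interest,
average the pixel intensities — yields per-gene, per-region expression
estimates that can be compared across brain regions. `hippaxis` implements
that workflow for a panel of endocrine receptor genes measured in the
hippocampus (HPC), cortex (CX) and cerebellum (CB) and in the hippocampal
subfields CA1, CA2, CA3 and the dentate gyrus (DG), together with the
statistical battery used to ask two questions:

1. Is the hippocampus the dominant site of endocrine receptor expression
   among comparable brain regions?
2. Within the hippocampus, are receptors for "challenge" ligands (stress,
   inflammation, blood-pressure fall; group A) segregated to DG, and
   receptors for "sufficiency" ligands (growth and abundance signals;
   group B) to the CA fields?

## The color scale and its inversion

The pseudocolor path is anchored at black (intensity 0), pure red (85),
pure yellow (170) and white (255) and is linear in RGB between anchors.
`color_scale()` materializes it as a 256-entry LUT. Because the 256 entries
are pairwise distinct, nearest-neighbour search in RGB inverts the scale
exactly for on-path colors; anti-aliased or compressed pixels map to the
closest on-path intensity (ties resolve to the lower intensity, a
convention that matters only for exactly equidistant colors). The true
atlas colormap may deviate from piecewise-linear between the four published
anchors; only the anchors are guaranteed.

`roi_mean()` averages decoded intensities over a rectangle ("cursor box",
0-based, top-left origin, half-open — the dominant raster convention) or a
mask label. The mean is linear in pixel intensities, permutation-invariant
and invariant to nearest-neighbour upscaling, which is why a 'mean' reading
rather than an integrated density is used: at constant image size the
relative values are identical. `quantify_atlas()` optionally measures each
region twice with independently jittered ROI placement, emulating two
researchers; discordant pairs (absolute difference above a tolerance,
default 5 intensity units) are flagged and resolved by averaging.

## Normalization, detection and prominence

Per gene, the region with the highest mean intensity is set to 100% and all
other regions are expressed relative to it (`normalize_profiles()`). This
removes probe-specific hybridization efficiency and is idempotent and
invariant to positive rescaling.

Detection (`call_detection()`) is thresholded: expressed iff mean ≥ τ, with
τ = 10 on the 0–255 scale by default. The published calls were made by eye,
so τ is exposed in the configuration and recorded in the run metadata; 10
is low enough to keep faint-but-real regional signal and high enough to
reject the truncated-noise floor of blank regions. Punctate or
irreproducible staining is operationalized as a pixel coefficient of
variation above a cutoff (default 3.0): a region whose signal comes from a
few bright specks has a much higher CV than a uniformly stained layer. The
published analysis gives no quantitative punctate rule; the CV rule is this
package's convention and only applies when per-ROI pixel statistics are
supplied.

Prominence over HPC/CX/CB (`classify_prominence()`): a gene expressed in
exactly one region is *exclusive* there; otherwise the region attaining the
per-gene maximum is *prominent*; exact ties yield *shared*, preferring no
region (the source analysis is silent on ties). Counts are tabulated
against two denominators: the full panel for detection fractions and the
brain-expressed subset for exclusivity/prominence fractions.

## The statistical battery

- `wilcoxon_paired()` — paired signed-rank test on raw intensities between
  two regions; zeros dropped, average ranks for ties; exact two-sided p for
  n ≤ 25 without ties, otherwise normal approximation with continuity
  correction. The gene universe defaults to genes detected in at least one
  of the three regions, and is configurable.
- `binomial_detected()` — whether two regions detect different numbers of
  genes. The published construction of this test is not fully specified;
  here it is an exact two-sided binomial test of k₁ successes in k₁ + k₂
  trials against p = 0.5, and the method label records that construction.
  On detected counts (86, 53) this gives p = 0.0064, in qualitative but not
  numerical agreement with the published 0.0101 — an expected consequence
  of the construction ambiguity, so the implemented p is reported, not
  forced.
- `chisq_equal()` — goodness of fit of exclusive (or prominent) counts
  against equal distribution across regions, no continuity correction.
- `bootstrap_correlation()` — Pearson correlation between subfields on
  arcsine-square-root transformed normalized values (the
  variance-stabilizing transform for percentages; values are divided by 100
  first because the transform needs proportions), with a case bootstrap:
  whole genes resampled with replacement, 10 000 replicates, percentile 95%
  interval. The percentile interval is chosen because the replicate count
  is large and the interval type was not published.
- `paired_t()` — pairwise subfield comparisons. Note that identical paired
  vectors are rejected as undefined (zero variance of differences) rather
  than reported as t = 0: a paired t statistic is 0/0 in that case.
- `dunn_sidak()` — per-comparison critical level 1 − (1 − α)^(1/m);
  0.0169 for three and 0.00851 for six comparisons at α = 0.05.

All tests are two-sided; sidedness was not published, and two-sided is the
conservative reading.

## The DG-vs-CA axis

For each informative gene, `compute_delta()` forms
Δ = log₁₀(DG + c) − log₁₀(meanCA + c) with meanCA the arithmetic mean of
CA1–CA3 (CA2 included; a configuration option excludes it) and c ∈ {1, 2}
added to accommodate zeros. Log base 10 is used; the fold summaries are
base-invariant. Group-level conclusions must be stable across both offsets
— the pipeline always computes the alternative offset and reports both.

`welch_t()` compares group A and B deltas with unequal-variance t and
fractional df. Because Δ may violate t-test assumptions,
`permutation_test()` confirms: the observed statistic is mean Δ(A) − mean
Δ(B); group labels are randomized 10 000 times preserving group sizes; the
two-sided p is (1 + #{|null| ≥ |observed|}) / (reps + 1). The add-one
smoothing avoids p = 0 from finite resampling; with 12 or fewer genes the
label assignments are enumerated exhaustively and the exact fraction is
returned instead.

Two fold summaries are reported. `fold_difference()` is the A-versus-B
contrast 10^(meanΔ(A) − meanΔ(B)). `enrichment_fold()` is its square root,
the geometric-mean within-group enrichment: under the symmetric synthetic
design (group A DG-enriched and group B CA-enriched by the same factor f)
the A−B contrast equals f², so the per-group enrichment — the quantity
comparable to a configured generator fold — is the square root. Recovery
studies measure `enrichment_fold()` on raw subfield intensities, where the
offset distortion is smallest; the normalized-scale delta table is what the
figures and group tests use.

`fpkm_axis()` repeats the analysis on RNA-seq subfield profiles: FPKM
values strictly below the 4-FPKM detection floor (the level that
corresponds to an undetectable hybridization signal) are zeroed — exactly
4 is retained — then the same delta/Welch/permutation machinery runs on
log(FPKM + offset).

## Ligand-effect comparison

Literature-coded effects of each receptor's ligand on long-term
potentiation and on neurogenesis are consumed as data: −1 inhibits, 0
mixed/none, +1 promotes, NA unknown. `group_mean_scores()` averages known
codes per group. `compare_groups()` tests group differences twice: a
Student's pooled-variance t on the full codes (0 included — it is
informative about effect magnitude), and a Pearson chi-square without
continuity correction on the 2×2 inhibition-versus-stimulation table (0 and
NA excluded, since that table contrasts direction only). How the original
analysis handled 0-coded entries is unstated; this split rule is the
package's documented convention. Degenerate inputs (zero pooled variance;
an empty 2×2 margin) make the corresponding test undefined; the other is
still returned.

## The synthetic atlas

`generate_profiles()` draws a 253-gene panel under the study conditions:
98 genes detectably expressed in brain, 86 of them in HPC, CX and CB
detection probabilities giving expected counts 76 and 53, and 32
informative genes split 16 challenge / 16 sufficiency. Informative genes
carry the configured subfield contrast: the weak side sits at intensity 24
(so the default 8.33-fold contrast places the enriched side at 199.92,
on-scale), group A enriched in DG and group B in CA. Uninformative
HPC-expressed genes get unstructured subfield expression around a base
intensity of 120. CX and CB levels are scaled to 0.6 and 0.45 of the
hippocampal base, encoding the reported hierarchy of expression levels
(HPC > CX > CB) that the cross-region tests probe. The per-gene HPC truth
is the mean of its four subfield truths, matching equal-area measurement of
the subfield union in the cartoon layout.

Noise is additive Gaussian on intensity, truncated to [0, 255] — the
simplest model consistent with bounded densitometry — with SD 5 by default;
atlas-style data give no replicate variance to estimate (typically one
animal per probe), so this is a convention, not an estimate. FPKM tables
are log-linearly coupled to the intensity truth
(log₁₀FPKM = −0.5 + 1.2·log₁₀(intensity + 1) + N(0, 0.2)), which lands
silent genes at ≈0.32 FPKM, safely below the 4-FPKM floor, and expressed
genes well above it. Effect codes agree with group membership with
probability 0.9 by default.

All randomness flows from one root seed, expanded into per-stage substreams
by hashing stage names (`substream_seed()`), so each stage is reproducible
in isolation and runs are byte-identical under a fixed seed.

What the generator does *not* emulate: real anatomy (the layout is a
cartoon of nested bands and blocks), probe chemistry, cell-type
composition, spatially correlated noise, or the long-tailed intensity
distributions of real atlases. Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct and
well-calibrated under its own assumptions — not that those assumptions hold
for any particular atlas.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at its full
253-gene default, permutation and bootstrap resampling at 10 000 replicates
for headline results, and reduced replicate counts (a few hundred) for
determinism and plumbing checks, where the replicate count is immaterial.
The bootstrap coverage property is checked at 1 000 replicates over 60
seeds. Exhaustive permutation enumeration replaces Monte-Carlo sampling at
12 genes or fewer. Comparisons of recovered to configured folds use a 15%
relative band, reflecting the sampling variability of 16-gene group means
at noise SD 5.

Degenerate inputs are surfaced as errors, not coerced: all-zero paired
differences (Wilcoxon, paired t), zero variance after the arcsine transform,
empty groups, empty ROIs, out-of-vocabulary regions, duplicate gene symbols
and out-of-range intensities all fail with located messages. Genes with
missing subfield values are excluded from the delta table with a logged
count.

## Known limitations

- The pseudocolor inversion assumes the published four-anchor, piecewise
  linear-in-RGB path; a different atlas colormap needs a different
  `color_scale()`.
- The punctate-CV detection rule and the binomial-test construction are
  documented conventions for under-specified published procedures.
- Reproducing the published statistics verbatim requires the study's
  per-gene supplementary tables transcribed to TSV (see
  `inst/extdata/README.md`); they are not redistributable with the
  package, so the corresponding check reports their absence explicitly.
- The ligand-effect stage consumes curated codes; no literature mining is
  attempted.
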