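Package: hippaxis
Title: Quantification of Endocrine Receptor Expression Across Mouse Brain
    Regions and the Hippocampal Challenge-Sufficiency Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify pseudocolored in situ hybridization images of
    endocrine receptor expression, normalize per-gene intensity profiles across
    brain regions (hippocampus, cortex, cerebellum) and hippocampal subfields
    (CA1, CA2, CA3, dentate gyrus), classify genes by detection, exclusivity and
    prominence, and test regional enrichment. Implements the dentate-gyrus versus
    cornu-ammonis log-ratio statistic for 'challenge' versus 'sufficiency'
    receptor groups with a two-stage permutation test, Welch and paired tests,
    case-bootstrap correlations on arcsine-square-root transformed values,
    Dunn-Sidak multiple-comparison correction, RNA-seq (FPKM) cross-validation
    with a detection floor, and comparison of ligand effects on long-term
    potentiation and neurogenesis. Includes a synthetic-atlas generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    boot,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
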