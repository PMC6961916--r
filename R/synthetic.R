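#' Configuration for the synthetic expression atlas
#'
#' Defines the study conditions the generator emulates: a panel of endocrine
#' receptor genes profiled across three brain regions (HPC, CX, CB) and four
#' hippocampal subfields (CA1, CA2, CA3, DG), with a small 'informative'
#' subset split into a DG-enriched challenge group (A) and a CA-enriched
#' sufficiency group (B). Defaults mirror the published study conditions:
#' 253 genes, 98/253 detectably expressed in brain, 86/253 in hippocampus,
#' 32 informative genes split 16/16, and an 8.33-fold subfield enrichment.
#'
#' @param n_genes Number of genes in the panel.
#' @param n_informative Number of informative genes (split between groups A
#'   and B); must not exceed the number of HPC-expressed genes.
#' @param n_group_a Number of informative genes assigned to group A
#'   (challenge); the remainder form group B.
#' @param dg_fold_A True DG/CA enrichment ratio for group A genes (> 0).
#' @param ca_fold_B True CA/DG enrichment ratio for group B genes (> 0).
#' @param base_intensity Mean intensity (0-255) of expressed, uninformative
#'   gene/region combinations before per-gene jitter.
#' @param subfield_base True intensity of the weak subfield of an informative
#'   gene; the enriched subfield sits at `subfield_base * fold`, truncated
#'   at 255. The default 24 keeps an 8.33-fold contrast on-scale (24 x 8.33
#'   = 199.92).
#' @param noise_sd SD of the additive Gaussian measurement noise, intensity
#'   units; observations are truncated to `[0, 255]`.
#' @param frac_brain_expressed Proportion of genes detectably expressed in at
#'   least one brain region.
#' @param frac_hpc_expressed Proportion of genes expressed in HPC (must not
#'   exceed `frac_brain_expressed`).
#' @param frac_cx_of_brain,frac_cb_of_brain Probability that a brain-expressed
#'   gene is expressed in CX / CB (defaults give expected counts 76 and 53).
#' @param cx_level,cb_level Expression level of CX / CB relative to the
#'   hippocampal `base_intensity`, encoding the reported hierarchy of
#'   expression levels (HPC > CX > CB).
#' @param effect_concordance Probability that an informative gene's coded
#'   ligand effect agrees with its group (A inhibits, B promotes).
#' @param seed Integer root seed; per-stage substreams are derived from it.
#' @return A validated list of class `hippaxis_syncfg`.
#' @export
synthetic_config <- function(n_genes = 253L,
                             n_informative = 32L,
                             n_group_a = 16L,
                             dg_fold_A = 8.33,
                             ca_fold_B = 8.33,
                             base_intensity = 120,
                             subfield_base = 24,
                             noise_sd = 5,
                             frac_brain_expressed = 98 / 253,
                             frac_hpc_expressed = 86 / 253,
                             frac_cx_of_brain = 76 / 98,
                             frac_cb_of_brain = 53 / 98,
                             cx_level = 0.6,
                             cb_level = 0.45,
                             effect_concordance = 0.9,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
    n_group_a = as.integer(n_group_a), dg_fold_A = dg_fold_A,
    ca_fold_B = ca_fold_B, base_intensity = base_intensity,
    subfield_base = subfield_base, noise_sd = noise_sd,
    frac_brain_expressed = frac_brain_expressed,
    frac_hpc_expressed = frac_hpc_expressed,
    frac_cx_of_brain = frac_cx_of_brain,
    frac_cb_of_brain = frac_cb_of_brain,
    cx_level = cx_level, cb_level = cb_level,
    effect_concordance = effect_concordance, seed = as.integer(seed)
  )
  if (cx_level <= 0 || cb_level <= 0) {
    stop("region levels must be positive", call. = FALSE)
  }
  props <- c(
    frac_brain_expressed, frac_hpc_expressed, frac_cx_of_brain,
    frac_cb_of_brain, effect_concordance
  )
  if (dg_fold_A <= 0 || ca_fold_B <= 0) {
    stop("enrichment folds must be positive", call. = FALSE)
  }
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_informative > cfg$n_genes) {
    stop("n_informative must not exceed n_genes", call. = FALSE)
  }
  if (cfg$n_group_a < 0 || cfg$n_group_a > cfg$n_informative) {
    stop("n_group_a must lie between 0 and n_informative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (base_intensity < 0 || base_intensity > 255 ||
      subfield_base < 0 || subfield_base > 255) {
    stop("base intensities must lie in [0, 255]", call. = FALSE)
  }
  if (frac_hpc_expressed > frac_brain_expressed) {
    stop("frac_hpc_expressed must not exceed frac_brain_expressed",
      call. = FALSE
    )
  }
  structure(cfg, class = "hippaxis_syncfg")
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Generate synthetic intensity profiles with ground truth
#'
#' Draws a gene panel under the configured study conditions. A fixed number
#' of genes is detectably expressed in brain; a subset of those in HPC; the
#' informative subset carries the configured DG-vs-CA contrast: group A genes
#' have true DG intensity `subfield_base * dg_fold_A` against a CA baseline
#' of `subfield_base`, group B the mirror image. Uninformative HPC-expressed
#' genes receive unstructured subfield expression. Observed intensities are
#' the true region means plus Gaussian noise, truncated to `[0, 255]`; the
#' per-gene HPC mean is the average of its four subfield truths (matching
#' equal-area measurement of the subfield union).
#'
#' @param config A [synthetic_config()].
#' @return A list with `profiles` (data frame: `gene`, then columns
#'   `r ALL_REGIONS` of observed mean intensities) and `truth` (data frame of
#'   true region means `true_*`, logical detection status `det_*` and the
#'   per-gene `group` label `"A"`, `"B"` or `"uninformative"`).
#' @export
generate_profiles <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "hippaxis_syncfg"))
  with_seed(substream_seed(config$seed, "profiles"), {
    n <- config$n_genes
    genes <- sprintf("gene%03d", seq_len(n))

    n_brain <- round(n * config$frac_brain_expressed)
    n_hpc <- round(n * config$frac_hpc_expressed)
    brain_idx <- sort(sample.int(n, n_brain))
    hpc_idx <- sort(sample(brain_idx, n_hpc))

    in_cx <- logical(n)
    in_cb <- logical(n)
    in_cx[brain_idx] <- stats::runif(n_brain) < config$frac_cx_of_brain
    in_cb[brain_idx] <- stats::runif(n_brain) < config$frac_cb_of_brain
    in_hpc <- seq_len(n) %in% hpc_idx
    # every brain-expressed gene must light up somewhere
    orphan <- setdiff(brain_idx, which(in_hpc | in_cx | in_cb))
    in_cx[orphan] <- TRUE

    group <- rep("uninformative", n)
    info_idx <- sort(sample(hpc_idx, config$n_informative))
    a_idx <- sort(sample(info_idx, config$n_group_a))
    b_idx <- setdiff(info_idx, a_idx)
    group[a_idx] <- "A"
    group[b_idx] <- "B"

    truth <- matrix(0, n, length(ALL_REGIONS),
      dimnames = list(genes, ALL_REGIONS)
    )
    jitter <- function(k) stats::runif(k, 0.6, 1.4)
    truth[in_cx, "CX"] <- clip255(
      config$cx_level * config$base_intensity * jitter(sum(in_cx))
    )
    truth[in_cb, "CB"] <- clip255(
      config$cb_level * config$base_intensity * jitter(sum(in_cb))
    )

    # uninformative HPC genes: unstructured subfield expression
    uninf_hpc <- setdiff(hpc_idx, info_idx)
    for (i in uninf_hpc) {
      on <- stats::runif(4) < 0.8
      if (!any(on)) on[sample.int(4, 1)] <- TRUE
      truth[i, HPC_SUBFIELDS[on]] <-
        clip255(config$base_intensity * jitter(sum(on)))
    }
    # informative genes carry the configured DG-vs-CA contrast
    lo <- config$subfield_base
    truth[a_idx, c("CA1", "CA2", "CA3")] <- lo
    truth[a_idx, "DG"] <- clip255(lo * config$dg_fold_A)
    truth[b_idx, c("CA1", "CA2", "CA3")] <- clip255(lo * config$ca_fold_B)
    truth[b_idx, "DG"] <- lo
    truth[, "HPC"] <- rowMeans(truth[, HPC_SUBFIELDS, drop = FALSE])

    observed <- truth
    observed[in_hpc | in_cx | in_cb, ] <- clip255(
      truth[in_hpc | in_cx | in_cb, , drop = FALSE] +
        stats::rnorm(
          sum(in_hpc | in_cx | in_cb) * ncol(truth),
          sd = config$noise_sd
        )
    )
    # zero-truth regions of expressed genes carry truncated noise (a real
    # image is never perfectly black); fully silent genes read 0 everywhere
    profiles <- data.frame(gene = genes, observed, row.names = NULL)
    truth_df <- data.frame(
      gene = genes, group = group,
      stats::setNames(as.data.frame(truth), paste0("true_", ALL_REGIONS)),
      stats::setNames(as.data.frame(truth > 0), paste0("det_", ALL_REGIONS)),
      row.names = NULL
    )
    list(profiles = profiles, truth = truth_df)
  })
}

#' Cartoon region layout for rendered atlas images
#'
#' A fixed, versioned geometry standing in for a sagittal section: four
#' equal-area horizontal bands for the hippocampal subfields CA1, CA2, CA3
#' and DG, plus two disjoint blocks for cortex and cerebellum. No anatomical
#' claim is made; equal subfield areas make the HPC union mean equal the
#' arithmetic mean of the subfield intensities.
#'
#' @param height,width Image dimensions in pixels.
#' @return An object of class `hippaxis_layout`: list with `mask` (integer
#'   `height x width` matrix, 0 = background) and `vocab` (named integer
#'   vector mapping region names to mask labels).
#' @export
atlas_layout <- function(height = 120L, width = 160L) {
  stopifnot(height >= 100, width >= 150)
  vocab <- c(CA1 = 1L, CA2 = 2L, CA3 = 3L, DG = 4L, CX = 5L, CB = 6L)
  mask <- matrix(0L, height, width)
  band <- function(rows, cols, label) mask[rows, cols] <<- label
  band(10:29, 10:69, vocab[["CA1"]])
  band(30:49, 10:69, vocab[["CA2"]])
  band(50:69, 10:69, vocab[["CA3"]])
  band(70:89, 10:69, vocab[["DG"]])
  band(10:89, 90:109, vocab[["CX"]])
  band(10:89, 120:139, vocab[["CB"]])
  structure(list(mask = mask, vocab = vocab), class = "hippaxis_layout")
}

#' Render an expression image from region intensities
#'
#' Paints each region of the layout with the forward pseudocolor of its
#' intensity, optionally perturbed per pixel by Gaussian noise in intensity
#' units (truncated to the 0-255 scale before color mapping). Background
#' pixels encode intensity 0 (black).
#'
#' @param intensities Named numeric vector of region intensities (0-255);
#'   every name must be a region of the layout.
#' @param layout An [atlas_layout()].
#' @param noise_sd Per-pixel Gaussian noise SD in intensity units.
#' @param seed Seed for the pixel noise.
#' @param scale A [color_scale()].
#' @return `height x width x 3` numeric array in `[0, 1]`, suitable for
#'   [png::writePNG()].
#' @export
render_image <- function(intensities, layout = atlas_layout(), noise_sd = 0,
                         seed = NULL, scale = color_scale()) {
  stopifnot(inherits(layout, "hippaxis_layout"))
  missing_regions <- setdiff(names(intensities), names(layout$vocab))
  if (length(missing_regions) > 0) {
    stop(
      "regions absent from layout: ", paste(missing_regions, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(intensities < 0 | intensities > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  mask <- layout$mask
  field <- matrix(0, nrow(mask), ncol(mask))
  for (rg in names(intensities)) {
    field[mask == layout$vocab[[rg]]] <- intensities[[rg]]
  }
  if (noise_sd > 0) {
    field <- with_seed(seed, {
      painted <- mask %in% layout$vocab[names(intensities)]
      field[painted] <- clip255(
        field[painted] + stats::rnorm(sum(painted), sd = noise_sd)
      )
      field
    })
  }
  rgb <- encode_intensity(as.vector(field), scale) / 255
  array(rgb, dim = c(nrow(mask), ncol(mask), 3))
}

#' Generate subfield FPKM tables coupled to intensity truth
#'
#' Emulates an RNA-seq cross-validation table: per-gene, per-subfield FPKM
#' values log-linearly coupled to the true hybridization intensity,
#' `log10(FPKM) = intercept + slope * log10(true intensity + 1) + noise`.
#' Genes with zero true intensity land below the 4-FPKM detection floor
#' (with the default intercept, at ~0.32 FPKM).
#'
#' @param truth Truth table from [generate_profiles()].
#' @param slope Positive coupling slope on the log10 scale.
#' @param intercept Intercept on the log10 FPKM scale.
#' @param log_noise_sd SD of Gaussian noise on log10(FPKM).
#' @param seed Integer seed.
#' @return Data frame: `gene`, then FPKM columns `CA1`, `CA2`, `CA3`, `DG`.
#' @export
generate_fpkm <- function(truth, slope = 1.2, intercept = -0.5,
                          log_noise_sd = 0.2, seed = 1L) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  tm <- as.matrix(truth[, paste0("true_", HPC_SUBFIELDS)])
  with_seed(seed, {
    lf <- intercept + slope * log10(tm + 1) +
      stats::rnorm(length(tm), sd = log_noise_sd)
    fpkm <- 10^lf
    out <- data.frame(gene = truth$gene, fpkm)
    names(out) <- c("gene", HPC_SUBFIELDS)
    out
  })
}

#' Generate coded ligand effects concordant with group labels
#'
#' Assigns literature-style effect codes for ligand action on long-term
#' potentiation and on neurogenesis: with probability `concordance` a group A
#' (challenge) gene is coded -1 (inhibits) and a group B (sufficiency) gene
#' +1 (promotes); otherwise the opposite sign. The two parameters are coded
#' independently. Uninformative genes are coded `NA` (unknown).
#'
#' @param truth Truth table from [generate_profiles()].
#' @param concordance Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame: `gene`, `group`, `ltp`, `neurogenesis` with codes
#'   -1 / +1 / `NA`.
#' @export
generate_effects <- function(truth, concordance = 0.9, seed = 1L) {
  if (concordance < 0 || concordance > 1) {
    stop("concordance must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    draw <- function(group) {
      code <- rep(NA_integer_, length(group))
      inf <- group %in% c("A", "B")
      expected <- ifelse(group[inf] == "A", -1L, 1L)
      agree <- stats::runif(sum(inf)) < concordance
      code[inf] <- ifelse(agree, expected, -expected)
      code
    }
    data.frame(
      gene = truth$gene,
      group = ifelse(truth$group %in% c("A", "B"), truth$group, NA),
      ltp = draw(truth$group),
      neurogenesis = draw(truth$group),
      row.names = NULL
    )
  })
}

#' Render the full synthetic atlas to PNG files
#'
#' Writes one pseudocolor PNG per gene (subfields plus CX/CB painted on the
#' cartoon layout), a grayscale label-mask PNG, and a JSON region vocabulary,
#' giving the image-quantification stage a complete file-based fixture.
#'
#' @param profiles Profile table from [generate_profiles()] (observed means).
#' @param dir Output directory, created if needed.
#' @param layout An [atlas_layout()].
#' @param noise_sd Per-pixel noise SD passed to [render_image()].
#' @param seed Integer root seed (one substream per gene).
#' @param genes Optional subset of gene names to render.
#' @return Invisibly, the directory path.
#' @export
write_atlas_images <- function(profiles, dir, layout = atlas_layout(),
                               noise_sd = 0, seed = 1L, genes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(genes)) genes <- profiles$gene
  rows <- match(genes, profiles$gene)
  if (anyNA(rows)) stop("unknown gene in `genes`", call. = FALSE)
  regions <- intersect(names(layout$vocab), names(profiles))
  for (k in seq_along(rows)) {
    vals <- unlist(profiles[rows[k], regions])
    img <- render_image(vals, layout, noise_sd,
      seed = substream_seed(seed, genes[k])
    )
    png::writePNG(img, file.path(dir, paste0(genes[k], ".png")))
  }
  png::writePNG(layout$mask / 255, file.path(dir, "mask.png"))
  jsonlite::write_json(as.list(layout$vocab), file.path(dir, "vocab.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a rendered atlas directory
#'
#' @param dir Directory written by [write_atlas_images()].
#' @return List with `images` (named list of gene image arrays), and the
#'   reconstructed `layout`.
#' @export
read_atlas_images <- function(dir) {
  vocab_path <- file.path(dir, "vocab.json")
  mask_path <- file.path(dir, "mask.png")
  if (!file.exists(vocab_path) || !file.exists(mask_path)) {
    stop("atlas directory must contain mask.png and vocab.json", call. = FALSE)
  }
  vocab <- unlist(jsonlite::read_json(vocab_path))
  mode(vocab) <- "integer"
  mask <- round(png::readPNG(mask_path) * 255)
  storage.mode(mask) <- "integer"
  files <- setdiff(list.files(dir, pattern = "\\.png$"), "mask.png")
  images <- lapply(file.path(dir, files), png::readPNG)
  names(images) <- sub("\\.png$", "", files)
  list(
    images = images,
    layout = structure(list(mask = mask, vocab = vocab),
      class = "hippaxis_layout"
    )
  )
}
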