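#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: input mode (synthetic
#' generation, pre-quantified tables, or pseudocolor images), file paths,
#' detection and punctate thresholds, the rater disparity tolerance, the FPKM
#' detection floor, the log offset, replicate counts for bootstrap and
#' permutation resampling, and the root seed from which all per-stage
#' substreams are derived.
#'
#' @param mode `"synthetic"`, `"tables"` or `"images"`.
#' @param intensity_path Intensity TSV (tables mode).
#' @param groups_path Optional TSV `gene`, `group` with labels A/B.
#' @param fpkm_path Optional subfield FPKM TSV.
#' @param effects_path Optional effects TSV (`gene`, `group`, `ltp`,
#'   `neurogenesis`).
#' @param images_dir Directory of per-gene PNGs plus `mask.png` and
#'   `vocab.json` (images mode).
#' @param detection_threshold Detection threshold on the 0-255 mean-intensity
#'   scale.
#' @param punctate_cv Pixel-CV cutoff above which signal is called punctate.
#' @param rater_tolerance Between-rater absolute difference flagged for
#'   review (images mode, 2 raters).
#' @param raters,jitter_px Rater count and ROI jitter for images mode.
#' @param fpkm_floor FPKM value below which RNA-seq expression counts as
#'   undetected.
#' @param offset Log offset (1 or 2) for the DG/CA delta.
#' @param bootstrap_reps,permutation_reps Resampling replicate counts.
#' @param wilcoxon_universe Gene universe for the pairwise region tests:
#'   `"brain"` (genes detected in at least one of HPC/CX/CB) or `"all"`.
#' @param seed Integer root seed.
#' @param synthetic A [synthetic_config()] (synthetic mode); its seed is
#'   overridden by `seed`.
#' @return A validated list of class `hippaxis_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "tables", "images"),
                            intensity_path = NULL, groups_path = NULL,
                            fpkm_path = NULL, effects_path = NULL,
                            images_dir = NULL,
                            detection_threshold = 10, punctate_cv = 3,
                            rater_tolerance = 5, raters = 1L, jitter_px = 0L,
                            fpkm_floor = 4, offset = 1,
                            bootstrap_reps = 10000L,
                            permutation_reps = 10000L,
                            wilcoxon_universe = c("brain", "all"),
                            seed = 1L,
                            synthetic = synthetic_config()) {
  mode <- match.arg(mode)
  wilcoxon_universe <- match.arg(wilcoxon_universe)
  if (bootstrap_reps < 1 || permutation_reps < 1) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (min(detection_threshold, punctate_cv, rater_tolerance, fpkm_floor) < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  paths <- c(
    intensity = intensity_path, groups = groups_path,
    fpkm = fpkm_path, effects = effects_path
  )
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) {
      stop("referenced file does not exist: ", p, call. = FALSE)
    }
  }
  if (mode == "tables" && is.null(intensity_path)) {
    stop("tables mode requires intensity_path", call. = FALSE)
  }
  if (mode == "images" &&
    (is.null(images_dir) || !dir.exists(images_dir))) {
    stop("images mode requires an existing images_dir", call. = FALSE)
  }
  synthetic$seed <- as.integer(seed)
  structure(
    list(
      mode = mode, intensity_path = intensity_path,
      groups_path = groups_path, fpkm_path = fpkm_path,
      effects_path = effects_path, images_dir = images_dir,
      detection_threshold = detection_threshold, punctate_cv = punctate_cv,
      rater_tolerance = rater_tolerance, raters = as.integer(raters),
      jitter_px = as.integer(jitter_px), fpkm_floor = fpkm_floor,
      offset = offset, bootstrap_reps = as.integer(bootstrap_reps),
      permutation_reps = as.integer(permutation_reps),
      wilcoxon_universe = wilcoxon_universe, seed = as.integer(seed),
      synthetic = synthetic
    ),
    class = "hippaxis_config"
  )
}

config_hash <- function(config) {
  stable_hash(paste(
    utils::capture.output(utils::str(unclass(config))),
    collapse = "\n"
  ))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — acquire intensities (generate, read, or
#' quantify images), normalize, call detection, classify prominence and
#' tabulate, run the cross-region statistical battery, run the DG-vs-CA axis
#' analysis, the FPKM cross-validation and the ligand-effect comparison —
#' skipping any stage whose inputs are absent with a logged notice. All
#' outputs are written as TSV/JSON into `out_dir` together with run metadata
#' (configuration hash, seed, package version). Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with all computed tables and test objects.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "hippaxis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message("[hippaxis] ", ...)
  res <- list(config = config)

  ## stage: acquire -----------------------------------------------------
  groups <- NULL
  fpkm <- NULL
  effects <- NULL
  truth <- NULL
  if (config$mode == "synthetic") {
    note("generating synthetic atlas (", config$synthetic$n_genes, " genes)")
    gen <- generate_profiles(config$synthetic)
    profiles <- gen$profiles
    truth <- gen$truth
    groups <- truth[truth$group %in% c("A", "B"), c("gene", "group")]
    fpkm <- generate_fpkm(truth, seed = substream_seed(config$seed, "fpkm"))
    effects <- generate_effects(truth,
      concordance = config$synthetic$effect_concordance,
      seed = substream_seed(config$seed, "effects")
    )
    write_gene_table(truth, file.path(out_dir, "truth.tsv"))
  } else if (config$mode == "tables") {
    note("reading intensity table ", config$intensity_path)
    profiles <- read_intensity_table(config$intensity_path)
  } else {
    note("quantifying images in ", config$images_dir)
    atlas <- read_atlas_images(config$images_dir)
    rois <- lapply(names(atlas$layout$vocab), roi_mask)
    q <- quantify_atlas(atlas$images, rois,
      layout = atlas$layout,
      raters = config$raters, jitter_px = config$jitter_px,
      tolerance = config$rater_tolerance,
      seed = substream_seed(config$seed, "quantify")
    )
    profiles <- q$profiles
    write_gene_table(q$flags, file.path(out_dir, "rater_flags.tsv"))
  }
  if (config$mode != "synthetic") {
    if (!is.null(config$groups_path)) {
      groups <- read_gene_table(config$groups_path)
    }
    if (!is.null(config$fpkm_path)) {
      fpkm <- read_gene_table(config$fpkm_path,
        numeric_cols = HPC_SUBFIELDS
      )
    }
    if (!is.null(config$effects_path)) {
      effects <- read_gene_table(config$effects_path)
    }
  }
  res$profiles <- profiles
  res$truth <- truth
  write_gene_table(profiles, file.path(out_dir, "intensity.tsv"))

  brain <- intersect(BRAIN_REGIONS, names(profiles))
  subf <- intersect(HPC_SUBFIELDS, names(profiles))

  ## stage: normalize + classify ---------------------------------------
  calls <- call_detection(profiles,
    threshold = config$detection_threshold,
    punctate_cv = config$punctate_cv
  )
  res$calls <- calls
  write_gene_table(calls, file.path(out_dir, "detection_calls.tsv"))
  if (length(brain) == 3) {
    norm_brain <- normalize_profiles(profiles, regions = brain)
    res$normalized_brain <- norm_brain
    write_gene_table(
      norm_brain[, c("gene", brain)],
      file.path(out_dir, "normalized_brain.tsv")
    )
    categories <- classify_prominence(calls, norm_brain, regions = brain)
    counts <- tabulate_counts(calls, categories, regions = brain)
    res$categories <- categories
    res$counts <- counts
    write_gene_table(categories, file.path(out_dir, "categories.tsv"))
    write_gene_table(counts, file.path(out_dir, "summary_counts.tsv"))
  } else {
    note("brain regions incomplete; prominence stage skipped")
  }
  if (length(subf) == 4) {
    norm_sub <- normalize_profiles(profiles, regions = subf)
    res$normalized_subfields <- norm_sub
    write_gene_table(
      norm_sub[, c("gene", subf)],
      file.path(out_dir, "normalized_subfields.tsv")
    )
  }

  ## stage: region statistics -------------------------------------------
  if (length(brain) == 3) {
    universe <- if (config$wilcoxon_universe == "brain") {
      genes_expr <- unique(calls$gene[calls$region %in% brain &
        calls$status == "expressed"])
      profiles$gene %in% genes_expr
    } else {
      rep(TRUE, nrow(profiles))
    }
    pairs <- list(
      c("HPC", "CX"), c("HPC", "CB"), c("CX", "CB")
    )
    pair_names <- vapply(pairs, paste, "", collapse = "_vs_")
    wilcox <- lapply(pairs, function(p) {
      wilcoxon_paired(profiles[universe, p[1]], profiles[universe, p[2]])
    })
    names(wilcox) <- paste0("wilcoxon_", pair_names)
    det_n <- vapply(
      brain,
      function(rg) {
        sum(calls$region == rg & calls$status == "expressed")
      },
      integer(1)
    )
    binom <- lapply(pairs, function(p) {
      binomial_detected(det_n[[p[1]]], det_n[[p[2]]])
    })
    names(binom) <- paste0("binomial_", pair_names)
    excl <- vapply(
      brain,
      function(rg) {
        sum(res$categories$category == "exclusive" &
          res$categories$region == rg, na.rm = TRUE)
      },
      integer(1)
    )
    prom <- vapply(
      brain,
      function(rg) {
        sum(res$categories$category %in% c("prominent", "exclusive") &
          res$categories$region == rg, na.rm = TRUE)
      },
      integer(1)
    )
    gof <- list(
      chisq_exclusive = chisq_equal(excl),
      chisq_prominent = chisq_equal(prom)
    )
    res$region_tests <- c(wilcox, binom, gof)
    res$p_crit <- c(three = dunn_sidak(0.05, 3), six = dunn_sidak(0.05, 6))
    region_tab <- bind_test_results(res$region_tests)
    write_gene_table(region_tab, file.path(out_dir, "region_tests.tsv"))
  }
  if (length(subf) == 4) {
    pairs <- utils::combn(subf, 2, simplify = FALSE)
    hpc_expr <- rowSums(as.matrix(profiles[, subf]) >=
      config$detection_threshold) > 0
    cors <- list()
    ptt <- list()
    for (p in pairs) {
      key <- paste(p, collapse = "_vs_")
      cors[[key]] <- tryCatch(
        bootstrap_correlation(
          res$normalized_subfields[hpc_expr, p[1]],
          res$normalized_subfields[hpc_expr, p[2]],
          reps = config$bootstrap_reps,
          seed = substream_seed(config$seed, paste0("boot_", key))
        ),
        error = function(e) e
      )
      ptt[[key]] <- tryCatch(
        paired_t(profiles[hpc_expr, p[1]], profiles[hpc_expr, p[2]]),
        error = function(e) e
      )
    }
    res$subfield_correlations <- cors
    res$subfield_paired_t <- ptt
    cor_tab <- do.call(rbind, lapply(names(cors), function(k) {
      x <- cors[[k]]
      if (inherits(x, "error")) {
        data.frame(
          comparison = k, r = NA, lower = NA, upper = NA,
          reps = NA, n = NA, note = conditionMessage(x)
        )
      } else {
        data.frame(
          comparison = k, r = x$estimate, lower = x$lower,
          upper = x$upper, reps = x$reps, n = x$n, note = ""
        )
      }
    }))
    write_gene_table(cor_tab, file.path(out_dir, "subfield_correlations.tsv"))
  }

  ## stage: DG-vs-CA axis -------------------------------------------------
  if (length(subf) == 4 && !is.null(groups) && nrow(groups) > 0) {
    delta <- compute_delta(res$normalized_subfields,
      groups = groups,
      offset = config$offset
    )
    g <- delta_groups(delta)
    res$delta <- delta
    res$axis <- list(
      welch = welch_t(g$a, g$b),
      permutation = permutation_test(delta,
        reps = config$permutation_reps,
        seed = substream_seed(config$seed, "permutation")
      ),
      fold_difference = fold_difference(delta),
      enrichment_fold = enrichment_fold(delta)
    )
    # offset-stability check at the alternative offset
    other <- if (config$offset == 1) 2 else 1
    delta2 <- compute_delta(res$normalized_subfields,
      groups = groups,
      offset = other
    )
    res$axis$other_offset <- list(
      offset = other,
      welch = welch_t(
        delta2$delta[delta2$group %in% "A"],
        delta2$delta[delta2$group %in% "B"]
      ),
      permutation = permutation_test(delta2,
        reps = config$permutation_reps,
        seed = substream_seed(config$seed, "permutation")
      )
    )
    write_gene_table(
      as.data.frame(delta),
      file.path(out_dir, "delta.tsv")
    )
    jsonlite::write_json(
      list(
        offset = config$offset,
        welch = unclass(res$axis$welch),
        permutation = unclass(res$axis$permutation),
        fold_difference = res$axis$fold_difference,
        enrichment_fold = res$axis$enrichment_fold,
        other_offset = list(
          offset = other,
          welch = unclass(res$axis$other_offset$welch),
          permutation = unclass(res$axis$other_offset$permutation)
        )
      ),
      file.path(out_dir, "axis_tests.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    note("axis stage skipped (needs subfields and group labels)")
  }

  ## stage: FPKM cross-validation ----------------------------------------
  if (!is.null(fpkm) && !is.null(groups) && nrow(groups) > 0) {
    res$fpkm <- fpkm_axis(fpkm, groups,
      floor = config$fpkm_floor,
      offset = config$offset, reps = config$permutation_reps,
      seed = substream_seed(config$seed, "fpkm_permutation")
    )
    write_gene_table(fpkm, file.path(out_dir, "fpkm.tsv"))
    write_gene_table(
      as.data.frame(res$fpkm$delta),
      file.path(out_dir, "fpkm_delta.tsv")
    )
  } else {
    note("FPKM stage skipped (no FPKM table or no groups)")
  }

  ## stage: ligand-effect comparison --------------------------------------
  if (!is.null(effects)) {
    res$effects <- list(
      table = effects,
      ltp = list(
        means = group_mean_scores(effects, "ltp"),
        tests = compare_groups(effects, "ltp")
      ),
      neurogenesis = list(
        means = group_mean_scores(effects, "neurogenesis"),
        tests = compare_groups(effects, "neurogenesis")
      )
    )
    write_gene_table(effects, file.path(out_dir, "effects.tsv"))
    eff_tab <- do.call(rbind, lapply(
      c("ltp", "neurogenesis"),
      function(par) {
        tt <- res$effects[[par]]$tests
        row <- function(which, x) {
          if (inherits(x, "error")) {
            data.frame(
              parameter = par, test = which, statistic = NA,
              df = NA, p_value = NA, note = conditionMessage(x)
            )
          } else {
            data.frame(
              parameter = par, test = which, statistic = x$statistic,
              df = x$df, p_value = x$p_value, note = ""
            )
          }
        }
        rbind(row("t", tt$t), row("chisq", tt$chisq))
      }
    ))
    write_gene_table(eff_tab, file.path(out_dir, "effect_tests.tsv"))
  } else {
    note("effect stage skipped (no effects table)")
  }

  ## metadata --------------------------------------------------------------
  jsonlite::write_json(
    list(
      package = "hippaxis",
      version = as.character(utils::packageVersion("hippaxis")),
      seed = config$seed,
      mode = config$mode,
      config_hash = config_hash(config),
      detection_threshold = config$detection_threshold,
      offset = config$offset,
      stages = names(res)
    ),
    file.path(out_dir, "metadata.json"),
    auto_unbox = TRUE
  )
  invisible(res)
}
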