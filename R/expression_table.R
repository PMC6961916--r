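#' Normalize intensity profiles to per-gene percent of maximum
#'
#' Within each gene, the region with the highest mean intensity is set to
#' 100% and the remaining regions are expressed as a percentage of that
#' maximum. The transformation removes per-probe hybridization efficiency so
#' that between-region patterns, not absolute signal, are compared. Genes
#' with zero intensity everywhere stay all-zero (and are not expressed).
#'
#' @param profiles Data frame with a `gene` column and numeric region
#'   columns on the 0-255 scale.
#' @param regions Region columns to normalize over; defaults to every known
#'   region column present. Normalization of the three whole-brain regions
#'   and of the four subfields are done as separate calls.
#' @return Data frame of the same shape with values in `[0, 100]`; attribute
#'   `not_expressed` lists genes that were all-zero across `regions`.
#' @export
normalize_profiles <- function(profiles, regions = NULL) {
  if (is.null(regions)) regions <- intersect(ALL_REGIONS, names(profiles))
  stopifnot(length(regions) >= 2, all(regions %in% names(profiles)))
  m <- as.matrix(profiles[, regions])
  if (any(m < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  mx <- apply(m, 1, max, na.rm = TRUE)
  scale <- ifelse(mx > 0, 100 / mx, 0)
  out <- profiles
  out[, regions] <- m * scale
  structure(out, not_expressed = profiles$gene[mx == 0])
}

#' Call per-region detection status
#'
#' A gene counts as expressed in a region when its mean intensity reaches the
#' detection threshold and, where per-ROI pixel statistics are available, the
#' pixel coefficient of variation does not exceed the punctate cutoff
#' (high-CV signal — a few bright specks in an otherwise blank field — is
#' classified as absent, mirroring the exclusion of punctate or
#' irreproducible staining).
#'
#' @param profiles Intensity table (`gene` + region columns, 0-255 scale).
#' @param threshold Detection threshold on the mean intensity; the boundary
#'   is inclusive (mean == threshold is expressed).
#' @param punctate_cv Maximum admissible pixel CV.
#' @param pixel_cv Optional data frame of the same shape as `profiles` giving
#'   the per-ROI pixel coefficient of variation.
#' @param regions Region columns to call; defaults to all present.
#' @return Long data frame: `gene`, `region`, `mean`, `status`
#'   (`"expressed"`/`"absent"`), `reason` (`"none"`, `"below-threshold"`,
#'   `"punctate"`).
#' @export
call_detection <- function(profiles, threshold = 10, punctate_cv = 3,
                           pixel_cv = NULL, regions = NULL) {
  stopifnot(threshold >= 0)
  if (is.null(regions)) regions <- intersect(ALL_REGIONS, names(profiles))
  out <- do.call(rbind, lapply(regions, function(rg) {
    mean_i <- profiles[[rg]]
    cv <- if (!is.null(pixel_cv)) pixel_cv[[rg]] else rep(NA_real_, length(mean_i))
    below <- mean_i < threshold
    punctate <- !below & !is.na(cv) & cv > punctate_cv
    reason <- ifelse(below, "below-threshold",
      ifelse(punctate, "punctate", "none")
    )
    data.frame(
      gene = profiles$gene, region = rg, mean = mean_i,
      status = ifelse(reason == "none", "expressed", "absent"),
      reason = reason, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Classify genes by exclusivity and prominence across brain regions
#'
#' Using the detection calls and normalized profiles over the three
#' whole-brain regions: a gene expressed in exactly one region is
#' `exclusive:<region>`; a gene expressed in several regions is
#' `prominent:<region>` for the region attaining its per-gene maximum; an
#' exact tie on the maximum yields `shared` (no region is preferred); a gene
#' expressed nowhere is `absent`.
#'
#' @param calls Detection calls from [call_detection()].
#' @param normalized Normalized profile table over the same regions.
#' @param regions The competing regions (default `BRAIN_REGIONS`).
#' @return Data frame: `gene`, `category` (`"exclusive"`, `"prominent"`,
#'   `"shared"`, `"absent"`), `region` (`NA` for shared/absent).
#' @export
classify_prominence <- function(calls, normalized,
                                regions = BRAIN_REGIONS) {
  present <- intersect(regions, unique(calls$region))
  if (length(present) < length(regions)) {
    warning(
      "classifying from available regions only: ",
      paste(present, collapse = ", ")
    )
  }
  genes <- normalized$gene
  expressed <- matrix(FALSE, length(genes), length(present),
    dimnames = list(genes, present)
  )
  sub <- calls[calls$region %in% present, ]
  expressed[cbind(match(sub$gene, genes), match(sub$region, present))] <-
    sub$status == "expressed"
  vals <- as.matrix(normalized[, present])
  cat_one <- function(i) {
    on <- which(expressed[i, ])
    if (length(on) == 0) {
      return(c("absent", NA))
    }
    if (length(on) == 1) {
      return(c("exclusive", present[on]))
    }
    v <- vals[i, on]
    top <- which(v == max(v))
    if (length(top) > 1) {
      return(c("shared", NA))
    }
    c("prominent", present[on[top]])
  }
  res <- t(vapply(seq_along(genes), cat_one, character(2)))
  data.frame(
    gene = genes, category = res[, 1], region = res[, 2],
    stringsAsFactors = FALSE
  )
}

#' Summary counts of detection, prominence and exclusivity
#'
#' Tabulates, per region: the number (and percentage of the full gene panel)
#' of genes detectably expressed there, and the numbers (and percentages of
#' brain-expressed genes) most prominently or exclusively expressed there.
#' A gene exclusive to a region counts as prominently expressed there too
#' (its maximum is attained in its only region).
#'
#' @param calls Detection calls over the brain regions.
#' @param categories Output of [classify_prominence()].
#' @param regions Regions to tabulate (default `BRAIN_REGIONS`).
#' @param n_total Panel size used as the detection denominator; defaults to
#'   the number of genes in `categories`.
#' @return Data frame with one row per region and columns `detected_n`,
#'   `detected_pct`, `prominent_n`, `prominent_pct`, `exclusive_n`,
#'   `exclusive_pct`; attributes `n_total` and `n_brain_expressed` carry the
#'   denominators.
#' @export
tabulate_counts <- function(calls, categories, regions = BRAIN_REGIONS,
                            n_total = nrow(categories)) {
  n_brain <- sum(categories$category != "absent")
  rows <- lapply(regions, function(rg) {
    det <- sum(calls$region == rg & calls$status == "expressed")
    prom <- sum(categories$category %in% c("prominent", "exclusive") &
      categories$region == rg, na.rm = TRUE)
    excl <- sum(categories$category == "exclusive" &
      categories$region == rg, na.rm = TRUE)
    pct <- function(k, d) if (d > 0) round(100 * k / d, 1) else 0
    data.frame(
      region = rg,
      detected_n = det, detected_pct = pct(det, n_total),
      prominent_n = prom, prominent_pct = pct(prom, n_brain),
      exclusive_n = excl, exclusive_pct = pct(excl, n_brain)
    )
  })
  structure(do.call(rbind, rows),
    n_total = n_total, n_brain_expressed = n_brain
  )
}
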