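#' Regions of interest
#'
#' Two ROI flavours mirror densitometry practice: a rectangle of constant
#' size ("cursor box") placed on the image, and a mask label fitted to a
#' region's exact extent. Rectangles use a 0-based, top-left-origin,
#' half-open convention: `roi_rect(x, y, w, h)` covers pixel columns
#' `x .. x+w-1` and rows `y .. y+h-1`.
#'
#' @param x,y 0-based column/row of the top-left corner.
#' @param width,height Extent in pixels (>= 1).
#' @param label Region name present in the layout vocabulary.
#' @param region Region name to report the measurement under (defaults to
#'   `label` for mask ROIs).
#' @return A list of class `hippaxis_roi`.
#' @name roi
NULL

#' @rdname roi
#' @export
roi_rect <- function(x, y, width, height, region) {
  stopifnot(width >= 1, height >= 1, x >= 0, y >= 0)
  structure(
    list(type = "rect", x = as.integer(x), y = as.integer(y),
         width = as.integer(width), height = as.integer(height),
         region = region),
    class = "hippaxis_roi"
  )
}

#' @rdname roi
#' @export
roi_mask <- function(label, region = label) {
  structure(list(type = "mask", label = label, region = region),
    class = "hippaxis_roi"
  )
}

# Linear pixel indices of an ROI within an image of the given dimensions,
# optionally translated by (dx, dy) pixels and clipped to the image bounds.
roi_indices <- function(roi, dim_hw, layout = NULL, dx = 0L, dy = 0L) {
  h <- dim_hw[1]
  w <- dim_hw[2]
  if (roi$type == "rect") {
    if (roi$x + roi$width > w || roi$y + roi$height > h) {
      stop("rectangle ROI exceeds image bounds", call. = FALSE)
    }
    cols <- pmin(pmax(roi$x + seq_len(roi$width) - 1L + dx, 0L), w - 1L)
    rows <- pmin(pmax(roi$y + seq_len(roi$height) - 1L + dy, 0L), h - 1L)
    idx <- as.vector(outer(rows + 1L, (cols) * h, `+`))
  } else {
    if (is.null(layout)) {
      stop("mask ROI requires a layout", call. = FALSE)
    }
    if (!roi$label %in% names(layout$vocab)) {
      stop("mask label not in layout vocabulary: ", roi$label, call. = FALSE)
    }
    idx <- which(layout$mask == layout$vocab[[roi$label]])
    if (dx != 0L || dy != 0L) {
      rows <- pmin(pmax((idx - 1L) %% h + dy, 0L), h - 1L)
      cols <- pmin(pmax((idx - 1L) %/% h + dx, 0L), w - 1L)
      idx <- cols * h + rows + 1L
    }
  }
  unique(idx)
}

#' Mean decoded intensity over a region of interest
#'
#' The surrogate for a densitometry 'Mean' measurement: every ROI pixel is
#' decoded through the pseudocolor LUT and the arithmetic mean of the decoded
#' intensities is returned. The mean is invariant to pixel order and to
#' duplicating the image at higher resolution with nearest-neighbour
#' upscaling (relative values are preserved at constant magnification).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param roi A [roi_rect()] or [roi_mask()].
#' @param scale A [color_scale()].
#' @param layout Layout (required for mask ROIs).
#' @return Mean intensity on the 0-255 scale.
#' @export
roi_mean <- function(image, roi, scale = color_scale(), layout = NULL) {
  stopifnot(inherits(roi, "hippaxis_roi"))
  idx <- roi_indices(roi, dim(image)[1:2], layout)
  if (length(idx) == 0) stop("empty ROI", call. = FALSE)
  h <- dim(image)[1]
  w <- dim(image)[2]
  px <- cbind(
    image[, , 1][idx], image[, , 2][idx], image[, , 3][idx]
  ) * 255
  mean(decode_intensity(px, scale))
}

#' Quantify a set of expression images
#'
#' Converts per-gene pseudocolor images into a gene x region intensity table.
#' Each requested region is measured by its ROI; with `raters = 2` every
#' measurement is repeated with an independently jittered ROI placement
#' (mimicking two researchers placing the cursor box), measurements differing
#' by more than `tolerance` intensity units are flagged for review, and the
#' reported value is the average of the two raters (the consensus rule).
#' The per-gene HPC value is the mean over the union of the four subfield
#' ROIs when all subfields are measured through mask ROIs of equal area,
#' which equals the mean of the subfield means.
#'
#' @param images Named list of image arrays (names are gene symbols).
#' @param rois List of ROIs covering the regions to measure.
#' @param scale A [color_scale()].
#' @param layout Layout for mask ROIs.
#' @param raters 1 or 2.
#' @param jitter_px Maximum absolute ROI translation (pixels) per rater when
#'   `raters = 2`.
#' @param tolerance Absolute between-rater difference (intensity units) above
#'   which a measurement is flagged.
#' @param seed Seed for the jitter.
#' @param derive_hpc If `TRUE` (default) and all four subfields are measured,
#'   add an `HPC` column as the mean of the subfield means.
#' @return List with `profiles` (data frame `gene` x regions) and `flags`
#'   (data frame `gene`, `region`, `rater1`, `rater2`, `flagged`).
#' @export
quantify_atlas <- function(images, rois, scale = color_scale(), layout = NULL,
                           raters = 1L, jitter_px = 0L, tolerance = 5,
                           seed = 1L, derive_hpc = TRUE) {
  stopifnot(raters %in% c(1L, 2L), length(images) > 0)
  genes <- names(images)
  regions <- vapply(rois, `[[`, "", "region")
  if (anyDuplicated(regions)) {
    stop("one ROI per region is required", call. = FALSE)
  }
  prof <- matrix(NA_real_, length(genes), length(regions),
    dimnames = list(genes, regions)
  )
  flags <- NULL
  with_seed(substream_seed(seed, "raters"), {
    for (g in seq_along(genes)) {
      img <- images[[g]]
      for (r in seq_along(rois)) {
        if (raters == 1L) {
          prof[g, r] <- roi_mean(img, rois[[r]], scale, layout)
        } else {
          m <- numeric(2)
          for (rat in 1:2) {
            dd <- if (jitter_px > 0) {
              sample(seq(-jitter_px, jitter_px), 2, replace = TRUE)
            } else {
              c(0L, 0L)
            }
            idx <- roi_indices(rois[[r]], dim(img)[1:2], layout,
              dx = dd[1], dy = dd[2]
            )
            px <- cbind(
              img[, , 1][idx], img[, , 2][idx], img[, , 3][idx]
            ) * 255
            m[rat] <- mean(decode_intensity(px, scale))
          }
          prof[g, r] <- mean(m)
          flags <- rbind(flags, data.frame(
            gene = genes[g], region = regions[r],
            rater1 = m[1], rater2 = m[2],
            flagged = abs(m[1] - m[2]) > tolerance
          ))
        }
      }
    }
  })
  out <- data.frame(gene = genes, prof, row.names = NULL)
  if (derive_hpc && all(HPC_SUBFIELDS %in% regions) && !"HPC" %in% regions) {
    out$HPC <- rowMeans(out[, HPC_SUBFIELDS])
    out <- out[, c("gene", intersect(ALL_REGIONS, names(out)))]
  }
  if (raters == 1L) {
    flags <- data.frame(
      gene = rep(genes, each = length(regions)),
      region = rep(regions, length(genes)),
      rater1 = NA_real_, rater2 = NA_real_, flagged = FALSE
    )
  }
  list(profiles = out, flags = flags)
}
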