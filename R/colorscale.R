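#' Pseudocolor scale of the expression images
#'
#' The atlas-style pseudocolor scale maps a 0-255 intensity onto a
#' black -> red -> yellow -> white path: black at 0, pure red at 85, pure
#' yellow at 170 and white at 255. Between the four anchors the path is
#' linear in RGB. `color_scale()` materializes the scale as the anchor table
#' plus a 256-entry lookup table (LUT); every LUT entry is a distinct RGB
#' triplet, so nearest-neighbour decoding inverts the scale exactly for
#' on-path colors.
#'
#' @param anchors Data frame with columns `intensity`, `r`, `g`, `b` giving
#'   the color-path anchors; intensities must be strictly increasing, start
#'   at 0 and end at 255. Defaults to the black/red/yellow/white scale.
#' @return An object of class `hippaxis_scale`: a list with the anchor table
#'   and `lut`, a 256 x 3 numeric matrix of RGB values in 0-255 (row `i`
#'   is the color for intensity `i - 1`).
#' @examples
#' sc <- color_scale()
#' sc$lut[1, ]    # black
#' sc$lut[86, ]   # pure red (intensity 85)
#' @export
color_scale <- function(anchors = NULL) {
  if (is.null(anchors)) {
    anchors <- data.frame(
      intensity = c(0, 85, 170, 255),
      r = c(0, 255, 255, 255),
      g = c(0, 0, 255, 255),
      b = c(0, 0, 0, 255)
    )
  }
  stopifnot(
    all(c("intensity", "r", "g", "b") %in% names(anchors)),
    all(diff(anchors$intensity) > 0),
    anchors$intensity[1] == 0,
    anchors$intensity[nrow(anchors)] == 255
  )
  lut <- round(encode_from_anchors(0:255, anchors))
  structure(list(anchors = anchors, lut = lut), class = "hippaxis_scale")
}

# Piecewise-linear interpolation of the color path; `intensity` may be
# fractional (rendering uses the continuous path, decoding the integer LUT).
encode_from_anchors <- function(intensity, anchors) {
  cbind(
    r = stats::approx(anchors$intensity, anchors$r, xout = intensity)$y,
    g = stats::approx(anchors$intensity, anchors$g, xout = intensity)$y,
    b = stats::approx(anchors$intensity, anchors$b, xout = intensity)$y
  )
}

#' Forward-map intensities to pseudocolors
#'
#' @param intensity Numeric vector of intensities in `[0, 255]` (fractional
#'   values follow the continuous color path).
#' @param scale A [color_scale()].
#' @return An `n x 3` matrix of RGB values in 0-255.
#' @export
encode_intensity <- function(intensity, scale = color_scale()) {
  stopifnot(inherits(scale, "hippaxis_scale"))
  if (any(intensity < 0 | intensity > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  encode_from_anchors(intensity, scale$anchors)
}

#' Invert the pseudocolor scale
#'
#' Decodes RGB pixels back to the 0-255 intensity scale by nearest-neighbour
#' search (Euclidean distance in RGB) against the 256-entry LUT. On-path
#' colors decode exactly; off-path colors (anti-aliasing, compression
#' artifacts) map to the closest on-path intensity, ties resolving to the
#' lower intensity.
#'
#' @param pixels An `n x 3` matrix (or length-3 vector) of RGB values in
#'   0-255.
#' @param scale A [color_scale()].
#' @return Integer vector of decoded intensities in 0-255.
#' @examples
#' decode_intensity(c(255, 255, 0)) # pure yellow -> 170
#' @export
decode_intensity <- function(pixels, scale = color_scale()) {
  stopifnot(inherits(scale, "hippaxis_scale"))
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 3, byrow = TRUE)
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 3)
  if (any(pixels < 0 | pixels > 255)) {
    stop("RGB components must lie in [0, 255]", call. = FALSE)
  }
  lut <- scale$lut
  # squared distance n x 256 via the expansion |p - l|^2 = |p|^2 - 2 p.l + |l|^2
  cross <- pixels %*% t(lut)
  d2 <- rowSums(pixels^2) - 2 * cross +
    matrix(rowSums(lut^2), nrow(pixels), 256, byrow = TRUE)
  max.col(-d2, ties.method = "first") - 1L
}

# Decode a [0,1]-valued H x W x 3 image array (as returned by png::readPNG)
# to an H x W intensity matrix on the 0-255 scale.
decode_image <- function(image, scale = color_scale()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  h <- dim(image)[1]
  w <- dim(image)[2]
  px <- cbind(
    as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3])
  ) * 255
  matrix(decode_intensity(px, scale), h, w)
}
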