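#' Validate an 8-bit RGB color image
#'
#' A color image is a `height x width x 3` numeric array with integral values
#' in `[0, 255]`. The third dimension holds the R, G and B channels.
#'
#' @param x array to validate.
#' @return `x`, invisibly classed as `color_image`.
#' @export
as_color_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("a color image must be a height x width x 3 array")
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("channel values must lie in [0, 255]")
  if (any(x != floor(x)))
    stop("channel values must be integral (8-bit)")
  class(x) <- c("color_image", class(array(0)))
  invisible(x)
}

check_color_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("expected a height x width x 3 RGB array")
  image
}

#' Direct luminance conversion of a color SWE image
#'
#' Collapses an RGB image to a single grayscale image with the perceptual
#' luminance weighting `0.2126 R + 0.7152 G + 0.0722 B`. The result is kept at
#' full real-valued precision (no 8-bit re-quantization) so that downstream
#' feature extraction is not degraded by a rounding step; use
#' [write_gray_png()] for an 8-bit export.
#'
#' The weights sum to 1, so achromatic pixels (`R = G = B = v`) map to `v`
#' exactly. The conversion is not injective: distinct colors with equal
#' luminance (metamers, e.g. `(50, 0, 0)` and `(0, 0, 147)`) collapse to
#' nearly identical gray values, which is the information loss the
#' three-channel decomposition avoids.
#'
#' @param image RGB array, `height x width x 3`, 8-bit values.
#' @return numeric matrix of luminance values in `[0, 255]`, with attribute
#'   `provenance = "direct"`.
#' @seealso [split_channels()], [recombine()]
#' @export
to_gray_direct <- function(image) {
  image <- check_color_image(image)
  r <- channel_matrix(image, 1)
  g <- channel_matrix(image, 2)
  b <- channel_matrix(image, 3)
  # algebraically identical to 0.2126 R + 0.7152 G + 0.0722 B, rearranged so
  # that achromatic pixels (R = G = B = v) map to v exactly in floating point
  out <- b + 0.2126 * (r - b) + 0.7152 * (g - b)
  attr(out, "provenance") <- "direct"
  out
}

# Channel as a matrix even for degenerate 1 x n / n x 1 images.
channel_matrix <- function(image, k) {
  matrix(image[, , k], dim(image)[1], dim(image)[2])
}

#' Split a color image into its three single-channel grayscale images
#'
#' The lossless alternative to luminance conversion: each output image is a
#' byte-identical copy of the corresponding source channel, so no color
#' information is discarded.
#'
#' @param image RGB array, `height x width x 3`, 8-bit values.
#' @return list with components `r`, `g`, `b`, each a numeric matrix carrying
#'   a `provenance` attribute (`"channel_R"` etc.).
#' @export
split_channels <- function(image) {
  image <- check_color_image(image)
  out <- list(r = channel_matrix(image, 1), g = channel_matrix(image, 2),
              b = channel_matrix(image, 3))
  attr(out$r, "provenance") <- "channel_R"
  attr(out$g, "provenance") <- "channel_G"
  attr(out$b, "provenance") <- "channel_B"
  class(out) <- "channel_triplet"
  out
}

#' Recombine three channel images into a color image
#'
#' Inverse of [split_channels()]: stacking the untouched channel images
#' reproduces the original image exactly, witnessing that the decomposition
#' is lossless.
#'
#' @param triplet list with components `r`, `g`, `b` (matrices of equal
#'   dimension, integral values in `[0, 255]`).
#' @return `height x width x 3` array.
#' @export
recombine <- function(triplet) {
  r <- triplet$r; g <- triplet$g; b <- triplet$b
  if (is.null(r) || is.null(g) || is.null(b))
    stop("triplet must have components r, g, b")
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    stop("channel dimensions do not match")
  vals <- c(r, g, b)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255) || any(vals != floor(vals)))
    stop("channel values must be integral in [0, 255]")
  out <- array(0L, dim = c(dim(r), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  storage.mode(out) <- "integer"
  out
}
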