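#' Rasterize a lesion contour polygon to a binary ROI mask
#'
#' Coordinates are `(row, col)` in a 0-based, row-major pixel grid; pixel
#' `(i, j)` is foreground iff its center `(i + 0.5, j + 0.5)` lies inside the
#' closed polygon by the even-odd (ray crossing) rule. This convention is
#' deliberately simple enough to verify by brute-force point-in-polygon
#' testing.
#'
#' @param vertices numeric matrix with >= 3 rows of `(row, col)` vertices
#'   (the polygon is closed implicitly).
#' @param height,width dimensions of the target image.
#' @return logical `height x width` matrix with at least one foreground
#'   pixel.
#' @export
polygon_to_mask <- function(vertices, height, width) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("a polygon needs at least 3 (row, col) vertices")
  y <- vertices[, 1]; x <- vertices[, 2]
  area2 <- sum(y * c(x[-1], x[1]) - c(y[-1], y[1]) * x)
  if (abs(area2) < .Machine$double.eps * 16)
    stop("degenerate polygon: zero area")
  py <- rep(seq_len(height) - 0.5, times = width)   # pixel-center rows
  px <- rep(seq_len(width) - 0.5, each = height)    # pixel-center cols
  inside <- rep(FALSE, height * width)
  n <- length(y)
  jj <- c(n, seq_len(n - 1L))
  for (i in seq_len(n)) {
    j <- jj[i]
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xi <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
      inside <- xor(inside, crosses & (px < xi))
    }
  }
  mask <- matrix(inside, height, width)
  if (!any(mask))
    stop("polygon covers no pixel centers inside the image")
  mask
}

#' Propagate one ROI mask across several derived images
#'
#' Extracts the foreground-pixel values of each image in a fixed row-major
#' order. Using the identical mask and ordering for the luminance image and
#' every single-channel image guarantees that feature differences between
#' channels are attributable to the intensities alone.
#'
#' @param mask logical matrix with >= 1 foreground pixel.
#' @param images a single matrix or a (optionally named) list of matrices,
#'   all matching the mask dimensions.
#' @return list of numeric vectors, one per image, each of length
#'   `sum(mask)` and in the same (row-major) pixel order.
#' @export
propagate <- function(mask, images) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("mask has no foreground pixels")
  if (is.matrix(images)) images <- list(images)
  idx <- which(t(mask))   # row-major ordering of foreground pixels
  lapply(images, function(img) {
    if (!identical(dim(img), dim(mask)))
      stop("image dimensions do not match the ROI mask")
    as.numeric(t(img)[idx])
  })
}
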