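#' Configuration for the synthetic elastogram generator
#'
#' Describes the study conditions emulated by [generate_cohort()]: a smooth
#' background stiffness field, one elliptical lesion per image, and a
#' dark-blue -> green -> red colormap over a fixed kPa display range, as on
#' clinical shear-wave elastography (SWE) overlays.
#'
#' Two modes are supported. In `"stiffness_contrast"` mode (the default) the
#' two lesion classes differ in mean stiffness, so both the luminance image
#' and the RGB channels carry the class signal. In `"metameric"` mode lesion
#' pixels of the two classes are painted with colors lying on a common
#' luminance isoline (`0.2126 R + 0.0722 B` constant at fixed G): the classes
#' are then strongly separable in the R (and B) channel but indistinguishable
#' after direct luminance conversion — the adversarial case for the direct
#' method.
#'
#' @param height,width image size in pixels (>= 32).
#' @param background_mean,background_sd background stiffness in kPa.
#' @param correlation_length spatial correlation length (Gaussian blur radius,
#'   pixels) of the background noise texture.
#' @param benign_mean,malignant_mean class mean lesion stiffness, kPa.
#' @param between_lesion_sd SD of the per-lesion mean stiffness around its
#'   class mean, kPa.
#' @param stiffness_sd within-lesion pixel SD, kPa.
#' @param vmin,vmax colormap display range in kPa (`vmin < vmax`).
#' @param mode `"stiffness_contrast"` or `"metameric"`.
#' @param metameric_benign,metameric_malignant length-2 vectors `(R, B)` of
#'   the class lesion colors used in metameric mode; the defaults lie on a
#'   common luminance isoline and keep both channels away from the 0/255
#'   clipping boundaries.
#' @param metameric_g baseline green level shared by both classes.
#' @param metameric_g_sd per-pixel SD of the green channel.
#' @param metameric_lesion_g_sd per-lesion SD of the mean green level.
#' @param metameric_achromatic_sd per-pixel SD of achromatic (equal in R, G,
#'   B) noise added in metameric mode.
#' @param axis_range range (pixels) from which lesion semi-axes are drawn.
#' @return object of class `swe_config`.
#' @export
swe_config <- function(height = 128, width = 128,
                       background_mean = 10, background_sd = 2,
                       correlation_length = 3,
                       benign_mean = 25, malignant_mean = 70,
                       between_lesion_sd = 6, stiffness_sd = 5,
                       vmin = 0, vmax = 100,
                       mode = c("stiffness_contrast", "metameric"),
                       metameric_benign = c(85, 30),
                       metameric_malignant = c(20, 221),
                       metameric_g = 80, metameric_g_sd = 8,
                       metameric_lesion_g_sd = 6,
                       metameric_achromatic_sd = 3,
                       axis_range = c(10, 25)) {
  mode <- match.arg(mode)
  if (height < 32 || width < 32) stop("image must be at least 32 x 32")
  if (!(vmin < vmax)) stop("colormap range requires vmin < vmax")
  stopifnot(background_sd >= 0, stiffness_sd >= 0, between_lesion_sd >= 0,
            length(metameric_benign) == 2, length(metameric_malignant) == 2)
  structure(list(
    height = height, width = width,
    background_mean = background_mean, background_sd = background_sd,
    correlation_length = correlation_length,
    benign_mean = benign_mean, malignant_mean = malignant_mean,
    between_lesion_sd = between_lesion_sd, stiffness_sd = stiffness_sd,
    vmin = vmin, vmax = vmax, mode = mode,
    metameric_benign = metameric_benign,
    metameric_malignant = metameric_malignant,
    metameric_g = metameric_g, metameric_g_sd = metameric_g_sd,
    metameric_lesion_g_sd = metameric_lesion_g_sd,
    metameric_achromatic_sd = metameric_achromatic_sd,
    axis_range = axis_range
  ), class = "swe_config")
}

#' Specify one elliptical lesion
#'
#' @param center length-2 `(row, col)` center in pixels (1-based centers of
#'   the pixel grid coordinate system).
#' @param semi_axes length-2 `(a, b)` semi-axes in pixels, each >= 5.
#' @param orientation rotation of the first axis, radians.
#' @param mean_stiffness,stiffness_sd lesion stiffness distribution, kPa.
#' @param label `"benign"` or `"malignant"`.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, orientation = 0,
                        mean_stiffness = 40, stiffness_sd = 5,
                        label = c("benign", "malignant")) {
  label <- match.arg(label)
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes < 5)) stop("lesion semi-axes must be >= 5 px")
  if (mean_stiffness < 0) stop("mean stiffness must be non-negative")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 orientation = orientation, mean_stiffness = mean_stiffness,
                 stiffness_sd = stiffness_sd, label = label),
            class = "lesion_spec")
}

# Logical mask of pixels whose centers fall inside the lesion ellipse.
ellipse_mask <- function(spec, height, width) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- rr - spec$center[1]
  dc <- cc - spec$center[2]
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- dr * co + dc * si
  v <- -dr * si + dc * co
  (u / spec$semi_axes[1])^2 + (v / spec$semi_axes[2])^2 <= 1
}

# Does the lesion ellipse fit fully inside the image? Conservative bound via
# the enclosing circle of radius max(a, b).
lesion_inside <- function(spec, height, width) {
  r <- max(spec$semi_axes)
  spec$center[1] - r >= 1 && spec$center[1] + r <= height &&
    spec$center[2] - r >= 1 && spec$center[2] + r <= width
}

# Spatially correlated standard-normal field: Gaussian blur of i.i.d. noise,
# renormalized by the kernel l2 norm so the marginal variance stays 1.
correlated_noise <- function(height, width, corr_len) {
  z <- matrix(stats::rnorm(height * width), height, width)
  if (corr_len <= 0) return(z)
  k <- gaussian_kernel_1d(corr_len)
  z <- sep_convolve(z, k, k)
  z / sqrt(sum(outer(k, k)^2))
}

#' Generate a stiffness field with one elliptical lesion
#'
#' Background pixels follow `N(background_mean, background_sd^2)` with
#' spatially correlated texture (Gaussian-smoothed white noise, blur radius =
#' `correlation_length`); pixels inside the lesion ellipse are i.i.d.
#' `N(mean_stiffness, stiffness_sd^2)`. Values are truncated at 0 kPa.
#'
#' @param config [swe_config()].
#' @param spec [lesion_spec()]; must lie fully inside the image.
#' @param seed integer seed; the field is a deterministic function of
#'   `(config, spec, seed)`.
#' @return numeric matrix of stiffness values (kPa) with attribute `mask`,
#'   the logical lesion mask.
#' @export
generate_field <- function(config, spec, seed = NULL) {
  stopifnot(inherits(config, "swe_config"), inherits(spec, "lesion_spec"))
  if (!lesion_inside(spec, config$height, config$width))
    stop("lesion ellipse extends outside the image bounds")
  with_seed(seed, {
    bg <- config$background_mean +
      config$background_sd * correlated_noise(config$height, config$width,
                                              config$correlation_length)
    mask <- ellipse_mask(spec, config$height, config$width)
    n_in <- sum(mask)
    field <- bg
    field[mask] <- stats::rnorm(n_in, spec$mean_stiffness, spec$stiffness_sd)
    field <- pmax(field, 0)
    attr(field, "mask") <- mask
    field
  })
}

#' Map a stiffness field to a color-coded SWE image
#'
#' Piecewise-linear colormap through the control points
#' `vmin -> (0, 0, 139)` (dark blue), `(vmin + vmax)/2 -> (0, 255, 0)`
#' (green) and `vmax -> (255, 0, 0)` (red), matching the qualitative
#' soft-to-stiff palette of clinical SWE displays. Values outside the range
#' are clipped; channels are quantized to 8 bits by round-half-up.
#'
#' @param field numeric matrix of stiffness values (kPa).
#' @param vmin,vmax display range, `vmin < vmax`.
#' @return `height x width x 3` integer array.
#' @export
colorize <- function(field, vmin = 0, vmax = 100) {
  if (!(vmin < vmax)) stop("colormap range requires vmin < vmax")
  x <- clamp(as.numeric(field), vmin, vmax)
  mid <- (vmin + vmax) / 2
  lo <- x <= mid
  t1 <- (x - vmin) / (mid - vmin)      # dark blue -> green
  t2 <- (x - mid) / (vmax - mid)       # green -> red
  r <- ifelse(lo, 0, 255 * t2)
  g <- ifelse(lo, 255 * t1, 255 * (1 - t2))
  b <- ifelse(lo, 139 * (1 - t1), 0)
  out <- array(0L, dim = c(dim(field), 3L))
  out[, , 1] <- round_half_up(r)
  out[, , 2] <- round_half_up(g)
  out[, , 3] <- round_half_up(b)
  out <- clamp(out, 0L, 255L)
  storage.mode(out) <- "integer"
  out
}

# Paint metameric lesion pixels over a colorized background image.
# Both classes share the green distribution and an achromatic per-pixel
# noise term; only the (R, B) balance differs, along a common luminance
# isoline, so the luminance image carries (almost) no class signal.
paint_metameric <- function(image, mask, config, label) {
  rb <- if (label == "malignant") config$metameric_malignant else config$metameric_benign
  n <- sum(mask)
  ach <- stats::rnorm(n, 0, config$metameric_achromatic_sd)
  gmu <- config$metameric_g + stats::rnorm(1, 0, config$metameric_lesion_g_sd)
  gpx <- gmu + stats::rnorm(n, 0, config$metameric_g_sd) + ach
  rch <- image[, , 1]; gch <- image[, , 2]; bch <- image[, , 3]
  rch[mask] <- clamp(round_half_up(rb[1] + ach), 0, 255)
  gch[mask] <- clamp(round_half_up(gpx), 0, 255)
  bch[mask] <- clamp(round_half_up(rb[2] + ach), 0, 255)
  out <- array(0L, dim = dim(image))
  out[, , 1] <- rch; out[, , 2] <- gch; out[, , 3] <- bch
  storage.mode(out) <- "integer"
  out
}

#' Generate a labelled cohort of synthetic color elastograms
#'
#' Draws `n_benign + n_malignant` single-lesion images under the stated
#' configuration. Lesion geometry (center, semi-axes, orientation) is
#' randomized within bounds; the ROI mask of each record equals the lesion
#' ellipse. The cohort is a deterministic function of `(config, counts,
#' seed)`.
#'
#' @param config [swe_config()].
#' @param n_benign,n_malignant requested class counts (each >= 1).
#' @param seed integer seed.
#' @return object of class `swe_cohort`: a list of records, each with
#'   elements `id`, `image` (RGB array), `mask` (logical matrix), `label`.
#' @export
generate_cohort <- function(config, n_benign, n_malignant, seed = NULL) {
  stopifnot(inherits(config, "swe_config"), n_benign >= 1, n_malignant >= 1)
  if (2 * config$axis_range[2] + 2 > min(config$height, config$width))
    stop("axis_range too large: the largest lesion cannot fit inside the image")
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  with_seed(seed, {
    records <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      lab <- labels[i]
      ax <- sort(stats::runif(2, config$axis_range[1], config$axis_range[2]),
                 decreasing = TRUE)
      r <- max(ax)
      ctr <- c(stats::runif(1, 1 + r, config$height - r),
               stats::runif(1, 1 + r, config$width - r))
      mu_cls <- if (lab == "malignant") config$malignant_mean else config$benign_mean
      mu <- clamp(mu_cls + stats::rnorm(1, 0, config$between_lesion_sd),
                  config$vmin, config$vmax)
      spec <- lesion_spec(ctr, ax, stats::runif(1, 0, pi),
                          mean_stiffness = mu,
                          stiffness_sd = config$stiffness_sd, label = lab)
      field <- generate_field(config, spec, seed = NULL)
      mask <- attr(field, "mask")
      image <- colorize(field, config$vmin, config$vmax)
      if (config$mode == "metameric")
        image <- paint_metameric(image, mask, config, lab)
      records[[i]] <- list(id = sprintf("lesion_%03d", i), image = image,
                           mask = mask, label = lab)
    }
    structure(records, class = "swe_cohort", config = config, seed = seed)
  })
}

#' @export
print.swe_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic SWE cohort: %d images (%d benign, %d malignant)\n",
              length(x), sum(labs == "benign"), sum(labs == "malignant")))
  cat(sprintf("  %d x %d px, mode = %s, colormap [%g, %g] kPa\n",
              cfg$height, cfg$width, cfg$mode, cfg$vmin, cfg$vmax))
  invisible(x)
}

#' Cohort labels as a 0/1 vector
#' @param cohort an `swe_cohort`.
#' @return integer vector, 0 = benign, 1 = malignant.
#' @export
cohort_labels <- function(cohort) {
  as_label01(vapply(cohort, `[[`, "", "label"))
}
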