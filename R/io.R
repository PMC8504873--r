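# File interchange: 8-bit PNG/TIFF images, 0/255 masks, JSON polygon
# records, CSV feature/score tables, JSON reports.

#' Read an 8-bit RGB color image
#'
#' Supports PNG and (if the tiff package is installed) TIFF. Images with an
#' alpha channel are rejected rather than silently flattened; grayscale
#' files are rejected because the pipeline's contract is an RGB input.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `height x width x 3` integer array with values in `0..255`.
#' @export
read_color_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L)
    stop("expected an RGB image, got ", paste(dim(raw), collapse = "x"))
  if (dim(raw)[3] == 4L)
    stop("images with an alpha channel are not accepted; flatten explicitly first")
  out <- round_half_up(raw[, , 1:3] * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit RGB color image as PNG
#' @param image `height x width x 3` array of 8-bit values.
#' @param path output path.
#' @export
write_color_png <- function(image, path) {
  image <- check_color_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a real-valued grayscale image as 8-bit PNG
#'
#' Quantizes with round-half-up and clips to `[0, 255]`. This export path is
#' separate from feature extraction, which always works on the full-precision
#' values.
#'
#' @param gray numeric matrix of intensities on the 0-255 scale.
#' @param path output path.
#' @export
write_gray_png <- function(gray, path) {
  q <- clamp(round_half_up(gray), 0, 255)
  png::writePNG(q / 255, path)
  invisible(path)
}

#' Read/write a binary ROI mask as single-channel PNG (255 = foreground)
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw >= 0.5
}

#' Read a lesion contour polygon from a JSON file
#'
#' The file holds a list of `[row, col]` vertex pairs in 0-based pixel
#' coordinates.
#'
#' @param path JSON file path.
#' @return numeric matrix of `(row, col)` vertices.
#' @export
read_roi_polygon <- function(path) {
  v <- jsonlite::fromJSON(path)
  v <- as.matrix(v)
  if (ncol(v) != 2L) stop("polygon file must contain [row, col] pairs")
  v
}

#' Write a synthetic cohort to disk
#'
#' Images as 8-bit RGB PNG, masks as single-channel 0/255 PNG, and a
#' manifest CSV with columns `id`, `image_path`, `mask_path`, `label`.
#'
#' @param cohort an `swe_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    ip <- file.path(dir, paste0(rec$id, ".png"))
    mp <- file.path(dir, paste0(rec$id, "_mask.png"))
    write_color_png(rec$image, ip)
    write_mask_png(rec$mask, mp)
    data.frame(id = rec$id, image_path = ip, mask_path = mp, label = rec$label)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a cohort from a manifest CSV
#' @param manifest path to a manifest written by [write_cohort()] (or of the
#'   same layout, for external data).
#' @return an `swe_cohort`-style list of records.
#' @export
read_cohort <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  records <- lapply(seq_len(nrow(df)), function(i) {
    list(id = df$id[i],
         image = read_color_image(resolve(df$image_path[i])),
         mask = read_mask_png(resolve(df$mask_path[i])),
         label = df$label[i])
  })
  class(records) <- "swe_cohort"
  records
}

#' Read/write a feature table as CSV
#' @param table a `feature_table`.
#' @param path CSV path; first columns are `id` and `label`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(df$id, df$label,
                as.matrix(df[, setdiff(colnames(df), c("id", "label")), drop = FALSE]))
}

#' Write per-lesion risk scores as CSV
#' @param id lesion ids.
#' @param label 0/1 labels.
#' @param score risk scores.
#' @param model,cohort identifying strings recorded per row.
#' @param path CSV path.
#' @export
write_scores_csv <- function(id, label, score, model, cohort, path) {
  utils::write.csv(data.frame(id = id, label = as_label01(label), score = score,
                              model = model, cohort = cohort),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export an object (run manifest, evaluation report) as JSON
#' @param x a list of scalars, vectors and data frames.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
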