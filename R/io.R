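#' Read a segmented crop-layer image
#'
#' Reads an 8-bit PNG or TIFF raster. RGB and RGBA are accepted (alpha is
#' dropped); a single-band image with values in \{0, 1\} or \{0, 255\} is
#' treated as a mask and expanded to an RGB layer so the same pipeline
#' applies.
#'
#' @param path Path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return An H x W x 3 numeric array with channel values in 0--255.
#' @export
read_layer_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read input image '%s'", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)",
                             ext)))
  raw <- raw * 255
  if (is.matrix(raw)) {
    vals <- unique(as.vector(raw))
    if (!all(vals %in% c(0, 1, 255)))
      stop("single-band input must be a {0,1} or {0,255} mask")
    m <- matrix(as.numeric(raw > 0) * 255, nrow(raw), ncol(raw))
    return(array(rep(m, 3L), dim = c(nrow(m), ncol(m), 3L)))
  }
  if (length(dim(raw)) != 3L || dim(raw)[3L] < 3L)
    stop("expected an RGB (or RGBA) raster")
  raw[, , 1:3, drop = FALSE]
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask A binary mask.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write a segmented RGB image as PNG
#'
#' @param img An H x W x 3 array with values in 0--255.
#' @param path Output path.
#' @export
write_layer_png <- function(img, path) {
  img <- as_segmented_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write detections to CSV
#'
#' Columns: id, row, col, area_px, equivalent_diameter_px,
#' captured_at_iteration. Coordinates are 1-based image (row, col) pixel
#' centers, stated in a comment header line.
#'
#' @param x An [agave_count][count_agaves] object or its detections frame.
#' @param path Output path.
#' @export
write_detections_csv <- function(x, path) {
  if (inherits(x, "agave_count")) x <- x$detections
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based (row, col) pixel centers", con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read detections written by [write_detections_csv()]
#' @param path CSV path.
#' @return A data frame of detections.
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read detections '%s'", path))
  utils::read.csv(path, comment.char = "#")
}

#' Read ground-truth plant centroids from CSV
#'
#' Expects columns \code{row} and \code{col} (1-based pixel coordinates).
#'
#' @param path CSV path.
#' @return A data frame with columns \code{row}, \code{col}.
#' @export
read_gt_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read ground truth '%s'", path))
  gt <- utils::read.csv(path, comment.char = "#")
  if (!all(c("row", "col") %in% names(gt)))
    stop(sprintf("malformed ground truth '%s': need columns 'row', 'col' (found: %s)",
                 path, paste(names(gt), collapse = ", ")))
  if (nrow(gt) && (anyNA(gt$row) || anyNA(gt$col)))
    stop(sprintf("malformed ground truth '%s': NA coordinates", path))
  gt[, c("row", "col")]
}

#' Write ground truth to CSV
#' @param gt Data frame with \code{row}, \code{col}.
#' @param path Output path.
#' @export
write_gt_csv <- function(gt, path) {
  utils::write.csv(gt[, c("row", "col")], path, row.names = FALSE)
  invisible(path)
}
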