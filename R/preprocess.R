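#' Luminance conversion of a segmented RGB layer
#'
#' Collapses the segmented crop layer to gray scale with the ITU-R BT.601
#' luma weights, \eqn{I = 0.299 R + 0.587 G + 0.114 B}. The result is kept in
#' floating point; no rounding happens before thresholding, so dim but
#' nonzero plant pixels are never lost.
#'
#' @param img A segmented image: an H x W x 3 numeric array with channel
#'   values in 0--255 (background black), as returned by
#'   [read_layer_image()] or [generate_field()].
#' @return An H x W numeric matrix with values in \[0, 255\].
#' @export
rgb_to_gray <- function(img) {
  img <- as_segmented_image(img)
  g <- 0.299 * img[, , 1L, drop = FALSE] + 0.587 * img[, , 2L, drop = FALSE] +
    0.114 * img[, , 3L, drop = FALSE]
  matrix(g, dim(img)[1L], dim(img)[2L])
}

as_segmented_image <- function(img) {
  if (is.matrix(img)) stop("expected an RGB array; for masks use binarize() directly")
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("a segmented image must be an H x W x 3 array")
  if (dim(img)[1L] < 1L || dim(img)[2L] < 1L) stop("empty image")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("channel values must lie in [0, 255]")
  img[, , 1:3, drop = FALSE]
}

#' Binarize a gray image
#'
#' Foreground is every strictly positive pixel: the upstream segmentation
#' paints background pure black, so any nonzero luminance is plant class.
#'
#' @param gray An H x W numeric matrix (e.g. from [rgb_to_gray()]), values in
#'   \[0, 255\].
#' @return A binary mask.
#' @export
binarize <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray)) stop("expected a numeric matrix")
  if (nrow(gray) < 1L || ncol(gray) < 1L) stop("empty image")
  if (anyNA(gray)) stop("gray image contains NA")
  matrix(as.integer(gray > 0), nrow(gray), ncol(gray))
}

#' Remove small isolated components ("clean")
#'
#' Deletes every 8-connected foreground component whose area is below
#' \code{min_area}. The default (2) removes exactly the isolated single
#' pixels left behind by the segmentation; larger speck removal is available
#' through \code{min_area} but is not the default.
#'
#' @param mask A binary mask.
#' @param min_area Minimum component area (pixels) to keep; must be >= 1.
#'   \code{min_area = 1} is the identity.
#' @return A binary mask, a subset of the input (anti-extensive).
#' @export
clean_mask <- function(mask, min_area = 2L) {
  mask <- as_binary_mask(mask)
  if (length(min_area) != 1L || !is.finite(min_area) || min_area < 1)
    stop("min_area must be >= 1")
  if (min_area == 1) return(mask)
  comp <- label_components(mask, connectivity = 8)
  drop <- comp$table$label[comp$table$area_px < min_area]
  if (length(drop)) {
    mask[comp$label_image %in% drop] <- 0L
  }
  mask
}

#' Fill enclosed background holes ("fill")
#'
#' Every background region not 4-connected to the image border becomes
#' foreground; border-connected background is kept. Foreground connectivity
#' is 8, background connectivity 4 — the standard dual pairing, so a ring of
#' 8-connected foreground always encloses its interior. Foreground never
#' shrinks (extensive).
#'
#' @param mask A binary mask.
#' @return A binary mask with all enclosed holes solid.
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  bg <- 1L - mask
  comp <- label_components(bg, connectivity = 4)
  if (nrow(comp$table) == 0L) return(mask)
  tab <- comp$table
  border <- tab$min_row == 1L | tab$min_col == 1L |
    tab$max_row == H | tab$max_col == W
  holes <- tab$label[!border]
  if (length(holes)) mask[comp$label_image %in% holes] <- 1L
  mask
}

#' Preprocess a segmented layer into the cleaned binary image Ic
#'
#' The full preprocessing chain: luminance conversion, strict-positive
#' binarization, removal of isolated specks, and filling of enclosed holes.
#' The result is the clean binary image that object separation and counting
#' operate on.
#'
#' @inheritParams rgb_to_gray
#' @param min_area Passed to [clean_mask()].
#' @return A binary mask (Ic).
#' @seealso [separate_objects()], [count_agaves()]
#' @export
preprocess <- function(img, min_area = 2L) {
  fill_holes(clean_mask(binarize(rgb_to_gray(img)), min_area = min_area))
}
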