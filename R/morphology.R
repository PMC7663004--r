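#' Binary erosion
#'
#' A pixel survives erosion iff every structuring-element offset lands on
#' foreground. Pixels outside the image are treated as background, so
#' foreground touching the frame is eroded from the border exactly like
#' interior foreground (no mirror padding).
#'
#' @param mask A binary mask (0/1 integer matrix).
#' @param se A [structuring element][make_se], or a \code{"shape:size"} string.
#' @return A binary mask of the same dimensions.
#' @export
erode <- function(mask, se) {
  mask <- as_binary_mask(mask)
  se <- parse_se(se)
  off <- se$offsets
  # pixel p is kept iff mask[p + o] == 1 for all offsets o,
  # i.e. the AND over shifts of mask by -o
  out <- shift_mask(mask, -off[1L, 1L], -off[1L, 2L])
  for (i in seq_len(nrow(off))[-1L]) {
    out <- out & shift_mask(mask, -off[i, 1L], -off[i, 2L])
  }
  m <- matrix(as.integer(out), nrow(mask), ncol(mask))
  m
}

#' Binary dilation
#'
#' A pixel is set iff some reflected structuring-element offset lands on
#' foreground (Minkowski sum). Outside-image pixels are background.
#'
#' @inheritParams erode
#' @return A binary mask of the same dimensions.
#' @export
dilate <- function(mask, se) {
  mask <- as_binary_mask(mask)
  se <- parse_se(se)
  off <- se$offsets
  out <- shift_mask(mask, off[1L, 1L], off[1L, 2L])
  for (i in seq_len(nrow(off))[-1L]) {
    out <- out | shift_mask(mask, off[i, 1L], off[i, 2L])
  }
  m <- matrix(as.integer(out), nrow(mask), ncol(mask))
  m
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same structuring element; removes
#' protrusions and thin bridges narrower than the element while preserving
#' object scale.
#'
#' @inheritParams erode
#' @return A binary mask.
#' @export
open_mask <- function(mask, se) {
  se <- parse_se(se)
  dilate(erode(mask, se), se)
}

#' Morphological closing
#'
#' Dilation followed by erosion with the same structuring element; fills gaps
#' and recovers patterns distorted by a preceding opening.
#'
#' @inheritParams erode
#' @return A binary mask.
#' @export
close_mask <- function(mask, se) {
  se <- parse_se(se)
  erode(dilate(mask, se), se)
}

#' Separate touching plants by opening then closing
#'
#' Applies opening followed by closing with the same structuring element
#' (default 3x3 square). The order matters: opening first cuts the thin
#' necks where neighbouring plants touch, then closing restores plant
#' bodies distorted by the opening without re-joining them.
#'
#' @param ic A cleaned binary mask, as produced by [preprocess()].
#' @param se Structuring element for both operations (default \code{"square:3"}).
#' @return A binary mask with attenuated plant overlap.
#' @export
separate_objects <- function(ic, se = make_se("square", 3)) {
  se <- parse_se(se)
  close_mask(open_mask(ic, se), se)
}
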