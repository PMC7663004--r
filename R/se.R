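#' Structuring elements for binary morphology
#'
#' Builds a flat (binary) structuring element as an origin-centered set of
#' \code{(dy, dx)} offsets. Two shapes are supported, the two used by the
#' counting pipeline: \code{"square"} (side length \code{size}, odd) and
#' \code{"diamond"} (city-block ball of radius \code{size}, the convention of
#' mainstream morphology toolboxes). The pipeline defaults are a 3x3 square
#' for opening/closing and a diamond of radius 2 (13 pixels) for the
#' iterative erosion.
#'
#' @param shape One of \code{"square"} or \code{"diamond"}.
#' @param size For \code{"square"}, the (odd) side length in pixels; for
#'   \code{"diamond"}, the radius, i.e. the maximum city-block distance from
#'   the center. A diamond of size 0 is the identity element.
#' @return An object of class \code{"structuring_element"}: a list with
#'   \code{shape}, \code{size} and \code{offsets} (an n x 2 integer matrix of
#'   \code{(dy, dx)} pairs containing the origin and symmetric under point
#'   reflection).
#' @examples
#' make_se("square", 3)    # 9 offsets
#' make_se("diamond", 2)   # 13 offsets
#' @seealso [erode()], [dilate()], [parse_se()]
#' @export
make_se <- function(shape = c("square", "diamond"), size) {
  shape <- match.arg(shape)
  if (length(size) != 1L || !is.finite(size) || size != as.integer(size))
    stop("'size' must be a single integer")
  size <- as.integer(size)
  if (shape == "square") {
    if (size < 1L) stop("square structuring element size must be >= 1")
    if (size %% 2L == 0L)
      stop("square structuring element size must be odd (no well-defined center)")
    h <- size %/% 2L
    g <- expand.grid(dy = -h:h, dx = -h:h)
  } else {
    if (size < 0L) stop("diamond structuring element size must be >= 0")
    g <- expand.grid(dy = -size:size, dx = -size:size)
    g <- g[abs(g$dy) + abs(g$dx) <= size, , drop = FALSE]
  }
  off <- as.matrix(g)
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  structure(list(shape = shape, size = size, offsets = off),
            class = "structuring_element")
}

#' Parse a "shape:size" structuring-element string
#'
#' Accepts the compact form used in configuration files and on the command
#' line, e.g. \code{"square:3"} or \code{"diamond:2"}.
#'
#' @param x A single string \code{"shape:size"}.
#' @return A \code{structuring_element}.
#' @export
parse_se <- function(x) {
  if (inherits(x, "structuring_element")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a 'shape:size' string, e.g. \"square:3\"")
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("malformed structuring element '%s'; expected 'shape:size'", x))
  size <- suppressWarnings(as.integer(parts[2L]))
  if (is.na(size))
    stop(sprintf("malformed structuring element size in '%s'", x))
  make_se(parts[1L], size)
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring element: %s, size %d (%d offsets)\n",
              x$shape, x$size, nrow(x$offsets)))
  invisible(x)
}

#' @export
format.structuring_element <- function(x, ...) {
  sprintf("%s:%d", x$shape, x$size)
}
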