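# Binary masks are plain integer matrices with values in {0, 1}.
# All morphology preserves dimensions; pixels outside the image are background.

#' Validate and coerce a binary mask
#'
#' @param x A matrix (logical or numeric) with values in \{0, 1\}.
#' @return An integer matrix with values 0/1.
#' @keywords internal
as_binary_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
    storage.mode(m) <- "integer"
    return(m)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("a binary mask must be a numeric or logical matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty image")
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop("a binary mask may only contain 0 and 1")
  storage.mode(x) <- "integer"
  x
}

# Shift a matrix by (dy, dx); vacated cells are 0 (outside-image = background).
shift_mask <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  if (abs(dy) >= H || abs(dx) >= W) return(matrix(0L, H, W))
  out <- matrix(0L, H, W)
  dr <- max(1L, 1L + dy):min(H, H + dy)   # destination rows
  dc <- max(1L, 1L + dx):min(W, W + dx)
  out[dr, dc] <- m[dr - dy, dc - dx]
  out
}
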