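# Connected-component labeling by run extraction + union-find.
# Runs are maximal vertical strips within a column (column-major scan);
# runs in adjacent columns are merged when their row intervals overlap
# (4-connectivity) or overlap within one pixel (8-connectivity).
# Final labels are renumbered 1..n by raster-scan order (row-major) of
# each component's first pixel, so labeling is deterministic.

#' Label connected components of a binary mask
#'
#' @param mask A binary mask (0/1 integer matrix).
#' @param connectivity Pixel adjacency: 8 (edges + diagonals, the default) or
#'   4 (edges only).
#' @return An object of class \code{"component_table"}: a list with
#'   \describe{
#'     \item{label_image}{integer matrix, 0 = background, labels 1..n}
#'     \item{table}{data frame with one row per component: \code{label},
#'       \code{area_px}, \code{equivalent_diameter_px}, \code{centroid_row},
#'       \code{centroid_col}, \code{min_row}, \code{min_col}, \code{max_row},
#'       \code{max_col}. Coordinates are 1-based matrix (row, col) indices.}
#'     \item{connectivity}{the adjacency used}
#'   }
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
#' nrow(label_components(m, 8)$table)  # 1: diagonal touch
#' nrow(label_components(m, 4)$table)  # 2
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_binary_mask(mask)
  if (length(connectivity) != 1L || !connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)

  fg <- which(mask == 1L)           # column-major indices, sorted
  if (length(fg) == 0L) {
    return(structure(list(label_image = matrix(0L, H, W),
                          table = empty_component_frame(),
                          connectivity = connectivity),
                     class = "component_table"))
  }
  r <- (fg - 1L) %% H + 1L
  cl <- (fg - 1L) %/% H + 1L

  # a new run starts when the column-major index jumps or the row resets to 1
  # (a jump of exactly 1 across a column boundary lands on row 1)
  newrun <- c(TRUE, diff(fg) != 1L)
  newrun[r == 1L] <- TRUE
  starts <- which(newrun)
  ends <- c(starts[-1L] - 1L, length(fg))
  nruns <- length(starts)
  run_col <- cl[starts]
  run_r1 <- r[starts]
  run_r2 <- r[ends]

  # union-find over runs (path halving)
  parent <- seq_len(nruns)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  slack <- if (connectivity == 8) 1L else 0L
  # runs are ordered by (col, r1); first/last run index of each column
  col_first <- match(seq_len(W), run_col)
  col_last <- length(run_col) + 1L - match(seq_len(W), rev(run_col))
  if (W >= 2L) {
    for (col in 2L:W) {
      i <- col_first[col - 1L]; j <- col_first[col]
      if (is.na(i) || is.na(j)) next
      i_end <- col_last[col - 1L]; j_end <- col_last[col]
      while (i <= i_end && j <= j_end) {
        if (run_r1[j] > run_r2[i] + slack) {
          i <- i + 1L
        } else if (run_r1[i] > run_r2[j] + slack) {
          j <- j + 1L
        } else {
          ri <- find_root(i); rj <- find_root(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          if (run_r2[i] < run_r2[j]) i <- i + 1L else j <- j + 1L
        }
      }
    }
  }

  root <- vapply(seq_len(nruns), find_root, integer(1))
  comp_of_run <- match(root, sort(unique(root)))
  ncomp <- max(comp_of_run)

  # deterministic renumbering: raster-scan (row-major) order of the first
  # pixel; the first pixel of run (r1, col) has row-major key (r1-1)*W + col
  run_key <- (run_r1 - 1) * W + run_col
  comp_key <- tapply_num(run_key, comp_of_run, ncomp, min)
  relabel <- integer(ncomp)
  relabel[order(comp_key)] <- seq_len(ncomp)

  lab_of_run <- relabel[comp_of_run]
  px_lab <- rep.int(lab_of_run, ends - starts + 1L)

  label_image <- matrix(0L, H, W)
  label_image[fg] <- px_lab

  area <- tabulate(px_lab, nbins = ncomp)
  sum_r <- as.numeric(rowsum(as.numeric(r), px_lab, reorder = TRUE))
  sum_c <- as.numeric(rowsum(as.numeric(cl), px_lab, reorder = TRUE))

  tab <- data.frame(
    label = seq_len(ncomp),
    area_px = area,
    equivalent_diameter_px = equivalent_diameter(area),
    centroid_row = sum_r / area,
    centroid_col = sum_c / area,
    min_row = as.integer(tapply_num(r, px_lab, ncomp, min)),
    min_col = as.integer(tapply_num(cl, px_lab, ncomp, min)),
    max_row = as.integer(tapply_num(r, px_lab, ncomp, max)),
    max_col = as.integer(tapply_num(cl, px_lab, ncomp, max))
  )
  structure(list(label_image = label_image, table = tab,
                 connectivity = connectivity),
            class = "component_table")
}

# group-wise aggregate with groups known to be 1..n
tapply_num <- function(x, g, n, fun) {
  out <- numeric(n)
  agg <- tapply(as.numeric(x), g, fun)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

empty_component_frame <- function() {
  data.frame(label = integer(), area_px = integer(),
             equivalent_diameter_px = numeric(),
             centroid_row = numeric(), centroid_col = numeric(),
             min_row = integer(), min_col = integer(),
             max_row = integer(), max_col = integer())
}

#' @export
print.component_table <- function(x, ...) {
  cat(sprintf("component table: %d component(s), %d-connectivity, %dx%d image\n",
              nrow(x$table), x$connectivity,
              nrow(x$label_image), ncol(x$label_image)))
  if (nrow(x$table)) print(utils::head(x$table, 10L), ...)
  if (nrow(x$table) > 10L) cat("...\n")
  invisible(x)
}

#' Equivalent diameter of a connected component
#'
#' The diameter of the circle whose area equals the component's pixel area:
#' \eqn{d = \sqrt{4A/\pi}}. This is the size feature thresholded by the
#' counting procedure.
#'
#' @param area_px Pixel area(s), positive.
#' @return Numeric vector of diameters in pixels.
#' @examples
#' equivalent_diameter(pi * 10^2)  # 20
#' @export
equivalent_diameter <- function(area_px) {
  if (length(area_px) == 0L) return(numeric())
  if (any(!is.finite(area_px)) || any(area_px <= 0))
    stop("area must be positive")
  sqrt(4 * area_px / pi)
}
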