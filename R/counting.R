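#' Configuration of the iterative counting procedure
#'
#' @param th_px Equivalent-diameter threshold Th in pixels (default 13, which
#'   corresponds to 39 cm on the ground at the 3 cm/px sampling distance of
#'   the survey flights; see [threshold_ground_cm()]).
#' @param erosion_se Structuring element for the iterative erosion (default
#'   \code{"diamond:2"}, the 13-pixel city-block ball).
#' @param opening_se Structuring element for the opening/closing separation
#'   step (default \code{"square:3"}).
#' @param connectivity Component adjacency, 4 or 8 (default 8).
#' @param max_iterations Safety cap on erosion passes (default 200; never
#'   binds on realistic fields, where the loop ends within a few dozen
#'   passes).
#' @param strict_less If \code{TRUE} (default) a component is harvested when
#'   its equivalent diameter is strictly below \code{th_px}; \code{FALSE}
#'   uses \code{<=}, for sensitivity analysis.
#' @param count_mode \code{"fragments"} (default) counts every harvested
#'   fragment; \code{"union"} counts connected components of the accumulated
#'   binary union of harvested fragments, which can merge fragments captured
#'   at different iterations that happen to touch. A divergence between the
#'   two is reported via [summary.agave_count()].
#' @return An object of class \code{"counting_config"}.
#' @export
counting_config <- function(th_px = 13,
                            erosion_se = make_se("diamond", 2),
                            opening_se = make_se("square", 3),
                            connectivity = 8,
                            max_iterations = 200L,
                            strict_less = TRUE,
                            count_mode = c("fragments", "union")) {
  if (length(th_px) != 1L || !is.finite(th_px) || th_px <= 0)
    stop("th_px must be a positive number")
  if (length(max_iterations) != 1L || !is.finite(max_iterations) ||
      max_iterations < 1)
    stop("max_iterations must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(th_px = th_px,
                 erosion_se = parse_se(erosion_se),
                 opening_se = parse_se(opening_se),
                 connectivity = as.integer(connectivity),
                 max_iterations = as.integer(max_iterations),
                 strict_less = isTRUE(strict_less),
                 count_mode = match.arg(count_mode)),
            class = "counting_config")
}

#' @export
print.counting_config <- function(x, ...) {
  cat(sprintf(paste0("counting config: Th = %g px (%s), erosion %s, ",
                     "opening %s, %d-connectivity, mode '%s'\n"),
              x$th_px, if (x$strict_less) "strict <" else "<=",
              format(x$erosion_se), format(x$opening_se),
              x$connectivity, x$count_mode))
  invisible(x)
}

#' Ground size of the diameter threshold
#'
#' Converts the pixel threshold to centimeters on the ground using the
#' ground sampling distance.
#'
#' @param th_px Threshold in pixels (default 13).
#' @param gsd_cm_per_px Ground sampling distance in cm/pixel (default 3).
#' @return Threshold in centimeters.
#' @examples
#' threshold_ground_cm()  # 39
#' @export
threshold_ground_cm <- function(th_px = 13, gsd_cm_per_px = 3) {
  th_px * gsd_cm_per_px
}

below_threshold <- function(d, cfg) {
  if (cfg$strict_less) d < cfg$th_px else d <= cfg$th_px
}

#' Split labeled components into small (IS) and large (IG) masks
#'
#' Components whose equivalent diameter is below Th are plant-sized
#' candidates and go to the IS mask; the remainder — overlapped clumps still
#' to be eroded — go to IG. The two masks partition the labeled foreground.
#'
#' @param comp A [component_table][label_components].
#' @param cfg A [counting_config()].
#' @return A list with binary masks \code{is_mask} and \code{ig_mask}.
#' @export
split_by_threshold <- function(comp, cfg = counting_config()) {
  if (!inherits(comp, "component_table"))
    stop("'comp' must come from label_components()")
  small <- comp$table$label[below_threshold(comp$table$equivalent_diameter_px, cfg)]
  lab <- comp$label_image
  is_mask <- matrix(0L, nrow(lab), ncol(lab))
  ig_mask <- is_mask
  if (length(small)) is_mask[lab %in% small] <- 1L
  ig_mask[lab > 0L & !(lab %in% small)] <- 1L
  list(is_mask = is_mask, ig_mask = ig_mask)
}

#' Count agave plants by iterative erosion
#'
#' The counting loop: label the connected components of the working image;
#' harvest every component whose equivalent diameter is below Th into the
#' accumulating image IS, recording the fragment's centroid, area and the
#' iteration of capture; erode what remains (IG) with the diamond
#' structuring element; repeat until IG is empty. The erosion pinches the
#' necks between overlapping plants so that clumps fall apart into
#' individually harvestable fragments; the plant count is the number of
#' harvested fragments.
#'
#' Harvest precedes erosion within each pass, so a component already below
#' threshold at iteration 1 is captured before any erosion touches it.
#' Recorded centroids and areas are those of the eroded fragment at capture
#' time; for roughly circular plants the symmetric erosion leaves the
#' centroid at the plant center.
#'
#' @param ic A binary mask, normally the output of [separate_objects()]
#'   applied to [preprocess()] output.
#' @param cfg A [counting_config()].
#' @return An object of class \code{"agave_count"}: a list with
#'   \describe{
#'     \item{detections}{data frame: \code{id}, \code{row}, \code{col}
#'       (1-based fragment centroid), \code{area_px},
#'       \code{equivalent_diameter_px}, \code{captured_at_iteration}
#'       (1-based loop pass)}
#'     \item{count}{the plant count under \code{cfg$count_mode}}
#'     \item{iterations_run}{number of loop passes executed}
#'     \item{is_mask}{binary union of all harvested fragments}
#'     \item{is_labels}{integer raster giving each harvested fragment its id}
#'     \item{partial}{TRUE if \code{max_iterations} was reached with
#'       foreground remaining (pathological input, e.g. a giant solid
#'       region); a warning is also raised}
#'     \item{iteration_log}{data frame of per-pass component and capture
#'       counts}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' m <- matrix(0L, 40, 40)
#' m[outer((1:40 - 20)^2, (1:40 - 20)^2, "+") <= 10^2] <- 1L
#' count_agaves(m)$count  # 1
#' @export
count_agaves <- function(ic, cfg = counting_config()) {
  ig <- as_binary_mask(ic)
  if (!inherits(cfg, "counting_config")) stop("'cfg' must be a counting_config")
  H <- nrow(ig); W <- ncol(ig)
  is_mask <- matrix(0L, H, W)
  is_labels <- matrix(0L, H, W)
  det <- vector("list", 64L)
  n_det <- 0L
  iter <- 0L
  partial <- FALSE
  log_rows <- list()

  repeat {
    comp <- label_components(ig, cfg$connectivity)
    ncomp <- nrow(comp$table)
    if (ncomp == 0L) break
    iter <- iter + 1L
    small <- below_threshold(comp$table$equivalent_diameter_px, cfg)
    if (any(small)) {
      sm <- comp$table[small, , drop = FALSE]
      keep_lab <- sm$label
      sel <- comp$label_image %in% keep_lab
      is_mask[sel] <- 1L
      # per-fragment ids in the label raster
      frag_ids <- n_det + seq_len(nrow(sm))
      is_labels[sel] <- frag_ids[match(comp$label_image[sel], keep_lab)]
      for (k in seq_len(nrow(sm))) {
        n_det <- n_det + 1L
        if (n_det > length(det)) det <- c(det, vector("list", length(det)))
        det[[n_det]] <- data.frame(
          id = n_det,
          row = sm$centroid_row[k],
          col = sm$centroid_col[k],
          area_px = sm$area_px[k],
          equivalent_diameter_px = sm$equivalent_diameter_px[k],
          captured_at_iteration = iter
        )
      }
      ig[sel] <- 0L
    }
    log_rows[[iter]] <- data.frame(iteration = iter, components = ncomp,
                                   captured = sum(small))
    if (all(small)) break            # IG empty, nothing left to erode
    if (iter >= cfg$max_iterations) {
      warning(sprintf(
        "max_iterations (%d) reached with foreground remaining; partial count",
        cfg$max_iterations))
      partial <- TRUE
      break
    }
    ig <- erode(ig, cfg$erosion_se)
  }

  detections <- if (n_det) do.call(rbind, det[seq_len(n_det)]) else
    data.frame(id = integer(), row = numeric(), col = numeric(),
               area_px = integer(), equivalent_diameter_px = numeric(),
               captured_at_iteration = integer())
  count <- if (cfg$count_mode == "union") {
    nrow(label_components(is_mask, cfg$connectivity)$table)
  } else {
    n_det
  }
  structure(list(detections = detections,
                 count = count,
                 iterations_run = iter,
                 is_mask = is_mask,
                 is_labels = is_labels,
                 partial = partial,
                 iteration_log = if (length(log_rows))
                   do.call(rbind, log_rows) else
                     data.frame(iteration = integer(), components = integer(),
                                captured = integer()),
                 config = cfg,
                 dim = c(H, W)),
            class = "agave_count")
}

#' @export
print.agave_count <- function(x, ...) {
  cat(sprintf("agave count: %d plant(s) in %d iteration(s) (%dx%d image)%s\n",
              x$count, x$iterations_run, x$dim[1L], x$dim[2L],
              if (x$partial) " [PARTIAL: iteration cap hit]" else ""))
  invisible(x)
}

#' @export
summary.agave_count <- function(object, ...) {
  union_count <- nrow(label_components(object$is_mask,
                                       object$config$connectivity)$table)
  out <- list(count = object$count,
              fragment_count = nrow(object$detections),
              union_count = union_count,
              iterations_run = object$iterations_run,
              partial = object$partial,
              iteration_log = object$iteration_log,
              config = object$config)
  class(out) <- "summary.agave_count"
  out
}

#' @export
print.summary.agave_count <- function(x, ...) {
  cat(sprintf("agave count: %d plant(s)\n", x$count))
  cat(sprintf("  fragments harvested: %d; union components: %d%s\n",
              x$fragment_count, x$union_count,
              if (x$fragment_count != x$union_count)
                " (touching fragments merged in union mode)" else ""))
  cat(sprintf("  iterations run: %d%s\n", x$iterations_run,
              if (x$partial) " [partial]" else ""))
  print(x$config)
  if (nrow(x$iteration_log)) {
    cat("  per-iteration components/captures:\n")
    print(x$iteration_log, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.agave_count <- function(x, ...) x$detections

#' Plot harvested detections over the accumulated IS image
#'
#' @param x An \code{agave_count} object.
#' @param gt Optional ground-truth data frame with \code{row}, \code{col};
#'   ground-truth points are overdrawn as open red circles.
#' @param ... Passed to [graphics::image()].
#' @export
plot.agave_count <- function(x, gt = NULL, ...) {
  m <- x$is_mask
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = c("black", "darkgreen"), axes = FALSE, asp = nrow(m) / ncol(m),
                  ...)
  H <- nrow(m); W <- ncol(m)
  if (nrow(x$detections)) {
    graphics::points((x$detections$col - 0.5) / W,
                     1 - (x$detections$row - 0.5) / H,
                     pch = 3, col = "green", cex = 0.6)
  }
  if (!is.null(gt) && nrow(gt)) {
    graphics::points((gt$col - 0.5) / W, 1 - (gt$row - 0.5) / H,
                     pch = 1, col = "red", cex = 0.8)
  }
  invisible(x)
}
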