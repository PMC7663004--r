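#' Run the full counting pipeline on a segmented layer
#'
#' Chains preprocessing (gray conversion, binarization, clean, fill),
#' opening-closing object separation, and the iterative erosion counter; if
#' ground truth is supplied, detections are matched and the accuracy metrics
#' computed. Optionally writes all artifacts (detections CSV, metrics and
#' run-summary JSON, intermediate masks, overlay image) to a directory.
#'
#' The pipeline is a pure function of the input pixels and the
#' configuration: repeated runs produce identical results.
#'
#' @param input Path to a PNG/TIFF segmented layer, an H x W x 3 array, or a
#'   [synthetic_field][generate_field] (whose own ground truth is then used
#'   unless \code{gt} overrides it).
#' @param gt Optional ground truth: a data frame with \code{row},
#'   \code{col}, or a path to such a CSV.
#' @param cfg A [counting_config()].
#' @param radius_px Matching radius for evaluation (default 17).
#' @param min_area Speck-removal threshold passed to [preprocess()].
#' @param out_dir Optional output directory; created if missing.
#' @param save_intermediate If \code{TRUE} (and \code{out_dir} is set),
#'   writes the binarized, cleaned and separated masks as 0/255 PNGs.
#' @param verbose If \code{TRUE}, logs per-iteration component counts.
#' @return A list with \code{count} (an \code{agave_count}),
#'   \code{metrics} (a [metrics_report()] or \code{NULL}) and \code{paths}
#'   (written files, if any).
#' @export
run_pipeline <- function(input, gt = NULL, cfg = counting_config(),
                         radius_px = 17, min_area = 2L,
                         out_dir = NULL, save_intermediate = FALSE,
                         verbose = FALSE) {
  if (inherits(input, "synthetic_field")) {
    if (is.null(gt)) gt <- input$gt
    img <- input$image
    input_name <- sprintf("synthetic(seed=%d)", input$spec$seed)
  } else if (is.character(input)) {
    img <- read_layer_image(input)
    input_name <- input
  } else {
    img <- as_segmented_image(input)
    input_name <- "<array>"
  }
  if (is.character(gt)) gt <- read_gt_csv(gt)

  gray <- rgb_to_gray(img)
  bin <- binarize(gray)
  ic <- fill_holes(clean_mask(bin, min_area = min_area))
  sep <- separate_objects(ic, cfg$opening_se)
  cnt <- count_agaves(sep, cfg)
  if (verbose) {
    apply(cnt$iteration_log, 1L, function(r)
      message(sprintf("iteration %d: %d component(s), %d captured",
                      r[["iteration"]], r[["components"]], r[["captured"]])))
  }

  metrics <- NULL
  if (!is.null(gt)) {
    metrics <- metrics_report(match_detections(cnt, gt, radius_px))
  }

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "detections.csv")
    write_detections_csv(cnt, p); paths <- c(paths, p)
    summary_json <- list(
      input = input_name,
      config = config_to_list(cfg),
      count = cnt$count,
      iterations_run = cnt$iterations_run,
      partial = cnt$partial
    )
    if (!is.null(metrics)) {
      summary_json$metrics <- metrics_to_list(metrics)
      p <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(metrics_to_list(metrics), p, auto_unbox = TRUE,
                           digits = NA)
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_json, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    if (save_intermediate) {
      for (nm in c("binarized", "cleaned", "separated", "is_mask")) {
        m <- switch(nm, binarized = bin, cleaned = ic, separated = sep,
                    is_mask = cnt$is_mask)
        p <- file.path(out_dir, paste0(nm, ".png"))
        write_mask_png(m, p); paths <- c(paths, p)
      }
    }
    p <- file.path(out_dir, "overlay.png")
    write_overlay_png(img, cnt, gt, radius_px, p); paths <- c(paths, p)
  }

  list(count = cnt, metrics = metrics, paths = paths)
}

config_to_list <- function(cfg) {
  list(th_px = cfg$th_px,
       erosion_se = format(cfg$erosion_se),
       opening_se = format(cfg$opening_se),
       connectivity = cfg$connectivity,
       max_iterations = cfg$max_iterations,
       strict_less = cfg$strict_less,
       count_mode = cfg$count_mode)
}

metrics_to_list <- function(m) {
  list(tp = m$counts$tp, fp = m$counts$fp, fn = m$counts$fn, gt = m$counts$gt,
       p_acc = m$p_acc, u_acc = m$u_acc, recall = m$recall, acc = m$acc)
}

#' Write a detection overlay image
#'
#' Draws the detections over the input layer: matched detections as green
#' crosses, unmatched detections (false positives) in purple, and missed
#' ground-truth plants in red — the usual visual convention for plant
#' counting surveys.
#'
#' @param img H x W x 3 array, values 0--255.
#' @param cnt An [agave_count][count_agaves] object.
#' @param gt Optional ground-truth data frame (\code{row}, \code{col});
#'   without it all detections are drawn green.
#' @param radius_px Matching radius used to classify detections.
#' @param path Output PNG path.
#' @export
write_overlay_png <- function(img, cnt, gt = NULL, radius_px = 17, path) {
  img <- img / 255
  H <- dim(img)[1L]; W <- dim(img)[2L]
  draw_cross <- function(im, r, c, rgb) {
    r <- round(r); c <- round(c)
    rr <- pmax(1L, r - 3L):pmin(H, r + 3L)
    cc <- pmax(1L, c - 3L):pmin(W, c + 3L)
    for (k in 1:3) {
      if (r >= 1 && r <= H) im[r, cc, k] <- rgb[k]
      if (c >= 1 && c <= W) im[rr, c, k] <- rgb[k]
    }
    im
  }
  det <- cnt$detections
  matched_det <- rep(TRUE, nrow(det))
  missed_gt <- NULL
  if (!is.null(gt) && nrow(det) && nrow(gt)) {
    # re-run the greedy matching to color by outcome
    dmat <- sqrt(outer(det$row, gt$row, "-")^2 + outer(det$col, gt$col, "-")^2)
    cand <- which(dmat <= radius_px, arr.ind = TRUE)
    det_used <- logical(nrow(det)); gt_used <- logical(nrow(gt))
    if (nrow(cand)) {
      for (k in order(dmat[cand])) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!det_used[i] && !gt_used[j]) {
          det_used[i] <- TRUE; gt_used[j] <- TRUE
        }
      }
    }
    matched_det <- det_used
    missed_gt <- gt[!gt_used, , drop = FALSE]
  }
  for (i in seq_len(nrow(det))) {
    col <- if (matched_det[i]) c(0, 1, 0) else c(0.6, 0, 0.8)
    img <- draw_cross(img, det$row[i], det$col[i], col)
  }
  if (!is.null(missed_gt)) {
    for (i in seq_len(nrow(missed_gt))) {
      img <- draw_cross(img, missed_gt$row[i], missed_gt$col[i], c(1, 0, 0))
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
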