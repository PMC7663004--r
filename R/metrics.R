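#' Match detections to ground-truth plant positions
#'
#' Greedy one-to-one matching by increasing centroid distance: candidate
#' (detection, ground truth) pairs within \code{radius_px} are sorted by
#' distance and accepted greedily, each detection and each ground-truth
#' point at most once. Matched pairs are true positives, unmatched
#' detections false positives, unmatched ground-truth points false
#' negatives. The default radius, 17 px, is about half the 1.0--1.2 m
#' in-row plant spacing at a 3 cm/px ground sampling distance, so a
#' detection is credited only if it lands closer to a plant than to its
#' neighbours.
#'
#' @param det An [agave_count][count_agaves] object, or a data frame with
#'   columns \code{row}, \code{col}.
#' @param gt A data frame (or 2-column matrix) of ground-truth centroids
#'   \code{row}, \code{col}.
#' @param radius_px Maximum centroid distance for a match (default 17).
#' @return An object of class \code{"confusion_counts"}: list with integer
#'   fields \code{tp}, \code{fp}, \code{fn}, \code{gt}; always satisfies
#'   \code{gt == tp + fn} and \code{tp + fp == } number of detections.
#' @export
match_detections <- function(det, gt, radius_px = 17) {
  if (inherits(det, "agave_count")) det <- det$detections
  det <- as.data.frame(det)
  gt <- as.data.frame(gt)
  if (nrow(gt) && !all(c("row", "col") %in% names(gt)))
    colnames(gt)[1:2] <- c("row", "col")
  if (length(radius_px) != 1L || !is.finite(radius_px) || radius_px <= 0)
    stop("radius_px must be positive")
  nd <- nrow(det); ng <- nrow(gt)
  if (nd == 0L || ng == 0L) {
    return(confusion_counts(tp = 0L, fp = nd, fn = ng))
  }
  dmat <- sqrt(outer(det$row, gt$row, "-")^2 + outer(det$col, gt$col, "-")^2)
  cand <- which(dmat <= radius_px, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand)) {
    ord <- order(dmat[cand])
    det_used <- logical(nd); gt_used <- logical(ng)
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!det_used[i] && !gt_used[j]) {
        det_used[i] <- TRUE
        gt_used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  confusion_counts(tp = tp, fp = nd - tp, fn = ng - tp)
}

#' Confusion counts for plant detection
#'
#' @param tp,fp,fn Nonnegative integers; the ground-truth total is
#'   \code{tp + fn}.
#' @param gt Optional explicit ground-truth total; must equal
#'   \code{tp + fn}.
#' @return An object of class \code{"confusion_counts"}.
#' @export
confusion_counts <- function(tp, fp, fn, gt = tp + fn) {
  vals <- c(tp = tp, fp = fp, fn = fn, gt = gt)
  if (anyNA(vals) || any(vals < 0) || any(vals != as.integer(vals)))
    stop("counts must be nonnegative integers")
  if (gt != tp + fn)
    stop("inconsistent counts: gt must equal tp + fn")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), gt = as.integer(gt)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, FN %d, GT %d\n",
              x$tp, x$fp, x$fn, x$gt))
  invisible(x)
}

as_confusion <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  if (is.list(c) && all(c("tp", "fp", "fn") %in% names(c)))
    return(confusion_counts(c$tp, c$fp, c$fn))
  stop("expected confusion counts (see confusion_counts())")
}

#' Producer's accuracy: fraction of true plants detected
#'
#' \eqn{P_{acc} = TP / GT}: of the plants an expert marked, the share the
#' algorithm found.
#'
#' @param c A [confusion_counts()] object.
#' @return A number in \[0, 1\].
#' @export
producer_accuracy <- function(c) {
  c <- as_confusion(c)
  if (c$gt == 0L) stop("no ground truth")
  c$tp / c$gt
}

#' User's accuracy: fraction of detections that are real plants
#'
#' \eqn{U_{acc} = TP / (TP + FP)}: the reliability of the detected plant
#' layer.
#'
#' @inheritParams producer_accuracy
#' @return A number in \[0, 1\].
#' @export
user_accuracy <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fp == 0L) stop("no detections")
  c$tp / (c$tp + c$fp)
}

#' Recall (true-positive rate)
#'
#' \eqn{recall = TP / (TP + FN)}; identical to producer's accuracy whenever
#' every ground-truth plant is either detected or missed (GT = TP + FN).
#'
#' @inheritParams producer_accuracy
#' @return A number in \[0, 1\].
#' @export
recall_metric <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fn == 0L) stop("no positives (tp + fn = 0)")
  c$tp / (c$tp + c$fn)
}

#' Average accuracy
#'
#' \eqn{Acc = (P_{acc} + U_{acc}) / 2}: balances missed plants against
#' spurious detections.
#'
#' @inheritParams producer_accuracy
#' @return A number in \[0, 1\].
#' @export
average_accuracy <- function(c) {
  (producer_accuracy(c) + user_accuracy(c)) / 2
}

#' Full metrics report for one region
#'
#' @inheritParams producer_accuracy
#' @return An object of class \code{"metrics_report"}: list with
#'   \code{p_acc}, \code{u_acc}, \code{recall}, \code{acc} and
#'   \code{counts}.
#' @export
metrics_report <- function(c) {
  c <- as_confusion(c)
  structure(list(p_acc = producer_accuracy(c),
                 u_acc = user_accuracy(c),
                 recall = recall_metric(c),
                 acc = average_accuracy(c),
                 counts = c),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  GT %d\n",
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$gt))
  cat(sprintf("Pacc %.*f  Uacc %.*f  recall %.*f  Acc %.*f\n",
              digits, x$p_acc, digits, x$u_acc, digits, x$recall,
              digits, x$acc))
  if (!is.null(x$macro_acc))
    cat(sprintf("macro-averaged Acc over regions: %.*f\n", digits, x$macro_acc))
  invisible(x)
}

#' Pool confusion counts over regions (micro-averaging)
#'
#' Sums TP/FP/FN/GT over regions and computes the four metrics on the pooled
#' counts. Micro-pooling weighs every plant equally; the macro-average of
#' per-region average accuracies — which weighs every region equally and in
#' general differs — is attached as \code{macro_acc} for comparison.
#'
#' @param counts A list of [confusion_counts()] objects (one per region).
#' @return A [metrics_report()] on the pooled counts, with the extra field
#'   \code{macro_acc}.
#' @export
pooled_summary <- function(counts) {
  if (!is.list(counts) || length(counts) == 0L ||
      inherits(counts, "confusion_counts"))
    stop("expected a nonempty list of confusion_counts")
  counts <- lapply(counts, as_confusion)
  tot <- confusion_counts(tp = sum(vapply(counts, `[[`, 0L, "tp")),
                          fp = sum(vapply(counts, `[[`, 0L, "fp")),
                          fn = sum(vapply(counts, `[[`, 0L, "fn")))
  rep <- metrics_report(tot)
  rep$macro_acc <- mean(vapply(counts, average_accuracy, 0))
  rep
}

#' Expert confusion counts for the nine surveyed field regions
#'
#' Per-region detection counts (TP, FN, FP and expert ground truth GT) from
#' the three-field blue-agave UAV survey the counting method was validated
#' on: three regions per field, plants verified by expert photo
#' interpretation. Useful for exercising the accuracy metrics without
#' imagery.
#'
#' @return A data frame with columns \code{region}, \code{tp}, \code{fn},
#'   \code{fp}, \code{gt}.
#' @examples
#' fc <- agave_field_counts()
#' pooled_summary(apply(fc, 1, function(r)
#'   confusion_counts(as.integer(r["tp"]), as.integer(r["fp"]),
#'                    as.integer(r["fn"]))))
#' @export
agave_field_counts <- function() {
  path <- system.file("extdata", "field_counts.csv", package = "agavecount",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
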