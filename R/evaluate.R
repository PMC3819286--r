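#' Evaluate a segmentation against ground truth
#'
#' Matches predicted segments to ground-truth nucleoli one-to-one by greedy
#' descending intersection-over-union (ties broken toward the lower
#' predicted label) and reports detection metrics. A match counts when its
#' IoU reaches `iou_threshold`.
#'
#' @param pred a `segment_labels` object or integer label array.
#' @param truth a `ground_truth` object or integer label array of true
#'   nucleoli.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return a list of class `segmentation_metrics`: `recall`, `precision`
#'   (reported as 0 with `precision_defined = FALSE` when there are no
#'   predictions), `mean_matched_iou`, `n_truth`, `n_pred`, `matches`
#'   (tibble of matched pairs with IoU) and `missed` (tibble of unmatched
#'   true nucleoli with their parent nucleus).
#' @export
evaluate_segmentation <- function(pred, truth, iou_threshold = 0.5) {
  pred_lab <- if (inherits(pred, "segment_labels")) pred$labels else pred
  truth_lab <- if (inherits(truth, "ground_truth")) truth$nucleolus_labels
               else truth
  parent <- if (inherits(truth, "ground_truth")) truth$parent_of else NULL
  if (!identical(dim(pred_lab), dim(truth_lab))) {
    stop("prediction and truth geometries differ", call. = FALSE)
  }
  n_truth <- if (length(truth_lab)) max(truth_lab) else 0L
  n_pred <- if (length(pred_lab)) max(pred_lab) else 0L

  empty_metrics <- function() {
    structure(list(recall = 0, precision = 0, precision_defined = n_pred > 0,
                   mean_matched_iou = NA_real_, n_truth = n_truth,
                   n_pred = n_pred,
                   matches = tibble::tibble(pred = integer(0),
                                            truth = integer(0),
                                            iou = numeric(0)),
                   missed = missed_tbl(seq_len(n_truth), parent)),
              class = "segmentation_metrics")
  }
  if (n_truth == 0L || n_pred == 0L) return(empty_metrics())

  nz <- pred_lab > 0L | truth_lab > 0L
  p <- pred_lab[nz]; t <- truth_lab[nz]
  inter <- table(factor(p, levels = 0:n_pred), factor(t, levels = 0:n_truth))
  area_p <- rowSums(inter)[-1] ; area_t <- colSums(inter)[-1]
  ov <- inter[-1, -1, drop = FALSE]
  iou <- ov / (outer(area_p, area_t, "+") - ov)

  pairs <- which(ov > 0, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-iou[pairs], pairs[, 1])
    pairs <- pairs[ord, , drop = FALSE]
  }
  used_p <- logical(n_pred); used_t <- logical(n_truth)
  mp <- integer(0); mt <- integer(0); mi <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_p[i] || used_t[j]) next
    if (iou[i, j] < iou_threshold) next
    used_p[i] <- TRUE; used_t[j] <- TRUE
    mp <- c(mp, i); mt <- c(mt, j); mi <- c(mi, iou[i, j])
  }
  structure(list(
    recall = length(mt) / n_truth,
    precision = length(mp) / n_pred,
    precision_defined = TRUE,
    mean_matched_iou = if (length(mi)) mean(mi) else NA_real_,
    n_truth = n_truth, n_pred = n_pred,
    matches = tibble::tibble(pred = mp, truth = mt, iou = mi),
    missed = missed_tbl(which(!used_t), parent)),
    class = "segmentation_metrics")
}

missed_tbl <- function(miss, parent) {
  tibble::tibble(
    nucleolus = as.integer(miss),
    parent_nucleus = if (is.null(parent)) NA_integer_
                     else as.integer(parent[as.character(miss)]))
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf(
    "<segmentation_metrics> recall %.3f, precision %.3f%s, mean IoU %.3f (%d true / %d predicted)\n",
    x$recall, x$precision,
    if (!x$precision_defined) " (no predictions)" else "",
    x$mean_matched_iou, x$n_truth, x$n_pred))
  invisible(x)
}
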