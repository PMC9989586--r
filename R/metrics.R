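# Confusion-count evaluation metrics for thresholded binary predictions.

#' Pixelwise confusion counts
#'
#' Thresholds the prediction at `pred >= threshold` and counts true/false
#' positives/negatives against a binary ground truth.
#'
#' @param pred Probability array/vector.
#' @param truth Binary array/vector of the same shape.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `gu_confusion` with integer `tp`, `tn`, `fp`,
#'   `fn`; the four counts sum to the number of pixels.
#' @export
confusion <- function(pred, truth, threshold = 0.5) {
  if (length(pred) != length(truth))
    stop("confusion: pred and truth must have the same shape")
  pb <- as.vector(pred) >= threshold
  tb <- as.vector(truth) >= 0.5
  structure(list(tp = sum(pb & tb), tn = sum(!pb & !tb),
                 fp = sum(pb & !tb), fn = sum(!pb & tb)),
            class = "gu_confusion")
}

#' Segmentation metrics from confusion counts
#'
#' Dice = `2TP/(2TP+FP+FN)`, IoU (Jaccard) = `TP/(TP+FP+FN)`,
#' precision = `TP/(TP+FP)`, recall = `TP/(TP+FN)`. Degenerate cases
#' follow the empty-mask convention: when `TP = FP = FN = 0` (both masks
#' empty) every metric is 1; a metric whose denominator is zero otherwise
#' is 0.
#'
#' @param c A [confusion()] result, or a list with `tp`, `fp`, `fn`
#'   (and optionally `tn`) entries.
#' @return Named list with `dice`, `iou`, `precision`, `recall`.
#' @export
seg_metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fp + fn == 0)
    return(list(dice = 1, iou = 1, precision = 1, recall = 1))
  list(
    dice = 2 * tp / (2 * tp + fp + fn),
    iou = tp / (tp + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0
  )
}
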