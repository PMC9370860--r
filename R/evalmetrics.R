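#' Pixel-wise confusion counts
#'
#' Tallies true/false positives/negatives between a predicted and a
#' ground-truth binary mask, with fruit (1) as the positive class. The four
#' counts always sum to the pixel count.
#'
#' @param pred,gt binary H x W matrices of identical shape.
#' @return A `confusion_counts` list with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, gt) {
  check_binary_mask(pred, "pred")
  check_binary_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stopf("pred (%d x %d) and gt (%d x %d) shapes differ",
          nrow(pred), ncol(pred), nrow(gt), ncol(gt))
  structure(list(tp = sum(pred == 1 & gt == 1),
                 tn = sum(pred == 0 & gt == 0),
                 fp = sum(pred == 1 & gt == 0),
                 fn = sum(pred == 0 & gt == 1)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(FN+TP), F1 = 2PR/(P+R). Degenerate cases follow
#' the empty-mask conventions: if TP = FP = FN = 0 (both masks empty) all
#' three are 1 (a fruitless frame predicted fruitless is a perfect
#' prediction); if TP = 0 with FP > 0 or FN > 0, an undefined member of
#' \{P, R\} is 0, and F1 is 0.
#'
#' @param c a `confusion_counts` object (or list with tp/fp/fn).
#' @return Named numeric vector `(precision, recall, f1)`, each in \[0, 1\].
#' @export
precision_recall_f1 <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp == 0 && fp == 0 && fn == 0)
    return(c(precision = 1, recall = 1, f1 = 1))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (fn + tp) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# Two-class (fruit / background) view of the confusion counts: for the
# background class the roles of fp and fn swap.
per_class_counts <- function(c) {
  list(fruit = list(tp = c$tp, fp = c$fp, fn = c$fn),
       background = list(tp = c$tn, fp = c$fn, fn = c$fp))
}

class_iou <- function(k) {
  denom <- k$tp + k$fp + k$fn
  if (denom == 0) 1 else k$tp / denom
}

#' Mean and ground-truth-weighted intersection over union
#'
#' Per-class IoU = TP/(TP+FP+FN) for fruit and background; `mean_iou` is
#' their unweighted average, `weighted_iou` weights each class IoU by its
#' ground-truth pixel share. A class absent from both masks scores IoU 1
#' (and weight 0 in the weighted variant).
#'
#' @param c a `confusion_counts` object.
#' @return Named vector `(mean_iou, weighted_iou)`.
#' @export
iou_metrics <- function(c) {
  k <- per_class_counts(c)
  iou_f <- class_iou(k$fruit)
  iou_b <- class_iou(k$background)
  total <- c$tp + c$tn + c$fp + c$fn
  share_f <- (c$tp + c$fn) / total
  share_b <- (c$tn + c$fp) / total
  c(mean_iou = (iou_f + iou_b) / 2,
    weighted_iou = share_f * iou_f + share_b * iou_b)
}

#' Global and mean (per-class) accuracy
#'
#' `global_accuracy` is the fraction of correctly classified pixels
#' regardless of class; `mean_accuracy` averages the per-class correct
#' fractions (per-class recall) over fruit and background. A class absent
#' from the ground truth contributes recall 1 when nothing was (wrongly)
#' taken from it, following the empty-class convention of
#' [precision_recall_f1()].
#'
#' @param c a `confusion_counts` object.
#' @return Named vector `(global_accuracy, mean_accuracy)`.
#' @export
accuracy_metrics <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  class_recall <- function(tp, fn) {
    if (tp + fn == 0) 1 else tp / (tp + fn)
  }
  c(global_accuracy = (c$tp + c$tn) / total,
    mean_accuracy = (class_recall(c$tp, c$fn) +
                       class_recall(c$tn, c$fp)) / 2)
}

image_metric_row <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  prf <- precision_recall_f1(cc)
  iou <- iou_metrics(cc)
  acc <- accuracy_metrics(cc)
  data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
             precision = prf[["precision"]], recall = prf[["recall"]],
             f1 = prf[["f1"]],
             global_accuracy = acc[["global_accuracy"]],
             mean_accuracy = acc[["mean_accuracy"]],
             mean_iou = iou[["mean_iou"]],
             weighted_iou = iou[["weighted_iou"]])
}

#' Evaluate a trained model on a labeled test set
#'
#' Predicts a mask for every test image and computes the full pixel-wise
#' metric suite. Headline numbers are per-image metrics averaged
#' arithmetically over the test set; aggregate-pixel metrics (computed on
#' the summed confusion counts) are reported alongside, as is the raw
#' aggregate confusion.
#'
#' @param model a trained model (see [train_model()]).
#' @param test non-empty list of [labeled_sample]s with ground-truth masks.
#' @return A `metrics_report`: list with `per_image` (one row per test
#'   image), `summary` (per-image averages), `aggregate` (metrics on summed
#'   counts) and `aggregate_confusion`.
#' @export
evaluate_test_set <- function(model, test) {
  if (!is.list(test) || length(test) == 0L)
    stopf("test set must be a non-empty list of labeled samples")
  preds <- lapply(test, function(s) predict_mask(model, s$image))
  evaluate_predictions(preds, test)
}

#' @rdname evaluate_test_set
#' @param preds list of predicted binary masks aligned with `test`.
#' @export
evaluate_predictions <- function(preds, test) {
  if (length(preds) != length(test))
    stopf("preds and test lengths differ")
  rows <- do.call(rbind, lapply(seq_along(test), function(i)
    cbind(data.frame(sample_id = test[[i]]$sample_id),
          image_metric_row(preds[[i]], test[[i]]$mask))))
  agg <- structure(list(tp = sum(rows$tp), tn = sum(rows$tn),
                        fp = sum(rows$fp), fn = sum(rows$fn)),
                   class = "confusion_counts")
  metric_cols <- c("precision", "recall", "f1", "global_accuracy",
                   "mean_accuracy", "mean_iou", "weighted_iou")
  summary <- colMeans(rows[, metric_cols])
  agg_metrics <- c(precision_recall_f1(agg), accuracy_metrics(agg),
                   iou_metrics(agg))
  structure(list(per_image = rows, summary = summary,
                 aggregate = agg_metrics[metric_cols],
                 aggregate_confusion = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %d images>\n", nrow(x$per_image)))
  cat("per-image averages (%):\n")
  print(round(100 * x$summary, 2))
  invisible(x)
}

#' Four-colour pixel-wise error map
#'
#' Encodes the comparison of a predicted and a ground-truth mask as an RGB
#' image: true positives white (255,255,255), true negatives black (0,0,0),
#' false negatives magenta (255,0,255), false positives green (0,255,0).
#'
#' @param pred,gt binary H x W matrices of identical shape.
#' @return H x W x 3 array of 8-bit intensities.
#' @export
error_map <- function(pred, gt) {
  check_binary_mask(pred, "pred")
  check_binary_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt))) stopf("pred and gt shapes differ")
  h <- nrow(pred); w <- ncol(pred)
  out <- array(0, c(h, w, 3))
  tp <- pred == 1 & gt == 1
  fn <- pred == 0 & gt == 1
  fp <- pred == 1 & gt == 0
  r <- matrix(0, h, w); g <- matrix(0, h, w); b <- matrix(0, h, w)
  r[tp | fn] <- 255
  g[tp | fp] <- 255
  b[tp | fn] <- 255
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
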