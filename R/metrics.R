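#' Per-class confusion counts for label volumes
#'
#' One-vs-rest tallies `TP_c, FP_c, FN_c, TN_c` for each class, plus
#' their micro sums over classes.  Exact integer arithmetic.
#'
#' @param pred Predicted label array (values in `0..n_classes-1`).
#' @param truth Ground-truth label array of the same shape.
#' @param n_classes Number of classes.
#' @return Object of class `confusion_counts`: `per_class` (data.frame
#'   with tp/fp/fn/tn per class), `micro` (named sums), `n_voxels`.
#' @export
confusion_counts <- function(pred, truth, n_classes = 4L) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    .stopf("'pred' and 'truth' differ in size")
  n_classes <- .check_count(n_classes, "n_classes", 2L)
  if (any(pred < 0L | pred >= n_classes) || any(truth < 0L | truth >= n_classes))
    .stopf("labels out of range [0, %d)", n_classes)
  n <- length(pred)
  # n_classes x n_classes table: rows = truth, cols = pred
  tab <- matrix(tabulate(truth * n_classes + pred + 1L, n_classes^2),
                nrow = n_classes, byrow = TRUE)
  tp <- diag(tab)
  fp <- as.integer(colSums(tab) - tp)   # predicted c, truth != c
  fn <- as.integer(rowSums(tab) - tp)
  tn <- n - tp - fp - fn
  per_class <- data.frame(class = 0:(n_classes - 1L),
                          tp = tp, fp = fp, fn = fn, tn = tn)
  structure(list(per_class = per_class,
                 micro = c(tp = sum(tp), fp = sum(fp), fn = sum(fn),
                           tn = sum(tn)),
                 n_voxels = n, n_classes = n_classes,
                 table = tab),
            class = "confusion_counts")
}

#' Overall accuracy (fraction of correctly labeled voxels)
#'
#' For pooled multi-class counts this is the voxel match fraction, the
#' sum of per-class true positives over the voxel count.
#'
#' @param counts A [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_voxels == 0L) .stopf("accuracy undefined: zero voxels")
  unname(counts$micro["tp"] / counts$n_voxels)
}

#' Accuracy from raw binary confusion counts
#'
#' The textbook arithmetic `(TP + TN) / (TP + TN + FP + FN)` applied to
#' explicitly supplied counts.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total <= 0) .stopf("accuracy undefined: zero total count")
  (tp + tn) / total
}

#' Mean intersection-over-union (macro over classes)
#'
#' Per class, `IoU_c = TP_c / (TP_c + FP_c + FN_c)`; the mean is taken
#' over all `n_classes`.  A class absent from both prediction and truth
#' (empty union) contributes IoU 1 by default (perfect agreement on an
#' empty set) and is flagged in the `empty_union_classes` attribute;
#' `empty_union = "skip"` drops such classes from the mean instead.
#'
#' @param pred,truth Label arrays, values in `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @param empty_union `"one"` (default) or `"skip"`.
#' @return Mean IoU with attributes `per_class` and
#'   `empty_union_classes`.
#' @export
mean_iou <- function(pred, truth, n_classes = 4L,
                     empty_union = c("one", "skip")) {
  empty_union <- match.arg(empty_union)
  cc <- confusion_counts(pred, truth, n_classes)
  pc <- cc$per_class
  union <- pc$tp + pc$fp + pc$fn
  iou <- ifelse(union > 0, pc$tp / union, 1)
  empty <- which(union == 0) - 1L
  m <- if (empty_union == "skip" && length(empty))
    mean(iou[union > 0]) else mean(iou)
  structure(m, per_class = iou, empty_union_classes = empty)
}

#' Dice similarity coefficient
#'
#' `mode = "global"` (default) flattens the one-hot encodings of
#' prediction and truth over all classes and voxels and computes
#' `2 * sum(pred * truth) / (sum(pred) + sum(truth))`; with soft
#' probability input (4D `(n_classes, ...)` array) this is the soft
#' Dice over all classes including background, the aggregation whose
#' magnitude sits far above the macro mean IoU on background-dominated
#' volumes.  `mode = "per_class"` returns `2|A_c n B_c|/(|A_c|+|B_c|)`
#' per class.
#'
#' @param pred Label array, or probability array `(n_classes, X, Y, Z)`.
#' @param truth Label array.
#' @param n_classes Number of classes.
#' @param mode `"global"` or `"per_class"`.
#' @return Global Dice scalar, or a per-class vector.
#' @export
dice_coefficient <- function(pred, truth, n_classes = 4L,
                             mode = c("global", "per_class")) {
  mode <- match.arg(mode)
  truth <- as.integer(truth)
  soft <- length(dim(pred)) == 4L
  if (soft) {
    if (dim(pred)[1L] != n_classes)
      .stopf("probability input must have %d channels", n_classes)
    pm <- matrix(pred, nrow = n_classes)
    if (ncol(pm) != length(truth)) .stopf("shape mismatch")
  } else {
    pred <- as.integer(pred)
    if (length(pred) != length(truth)) .stopf("shape mismatch")
  }
  if (mode == "global") {
    if (soft) {
      overlap <- sum(pm[cbind(truth + 1L, seq_along(truth))])
      return(2 * overlap / (sum(pm) + length(truth)))
    }
    # hard one-hot: 2*matches / (n + n)
    return(2 * sum(pred == truth) / (2 * length(truth)))
  }
  if (soft) pred <- max.col(t(pm), ties.method = "first") - 1L
  vapply(0:(n_classes - 1L), function(c) {
    a <- pred == c; b <- truth == c
    den <- sum(a) + sum(b)
    if (den == 0) 1 else 2 * sum(a & b) / den
  }, numeric(1))
}

.ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Precision, sensitivity and specificity from pooled counts
#'
#' Micro one-vs-rest aggregation over classes by default:
#' `TP/(TP+FP)`, `TP/(TP+FN)` and `TN/(TN+FP)` on the summed counts.
#' A zero denominator yields `NA` (an explicit undefined marker), never
#' a silent 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- counts$micro
  unname(.ratio_or_na(m["tp"], m["tp"] + m["fp"]))
}

#' @rdname precision
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- counts$micro
  unname(.ratio_or_na(m["tp"], m["tp"] + m["fn"]))
}

#' @rdname precision
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- counts$micro
  unname(.ratio_or_na(m["tn"], m["tn"] + m["fp"]))
}

#' Full six-metric segmentation report
#'
#' Computes accuracy, mean IoU (macro), Dice (global), precision,
#' sensitivity and specificity (micro one-vs-rest), plus per-class IoU,
#' with the aggregation conventions recorded in the report.
#'
#' @param pred Label array or probability array `(n_classes, ...)`.
#' @param truth Label array.
#' @param n_classes Number of classes.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(pred, truth, n_classes = 4L) {
  soft <- length(dim(pred)) == 4L && dim(pred)[1L] == n_classes
  hard <- if (soft) array(max.col(t(matrix(pred, nrow = n_classes)),
                          ties.method = "first") - 1L,
                          dim(pred)[-1L]) else pred
  cc <- confusion_counts(hard, truth, n_classes)
  miou <- mean_iou(hard, truth, n_classes)
  structure(list(
    accuracy = accuracy(cc),
    mean_iou = as.numeric(miou),
    dice_coef = dice_coefficient(pred, truth, n_classes, mode = "global"),
    precision = precision(cc),
    sensitivity = sensitivity(cc),
    specificity = specificity(cc),
    per_class_iou = as.numeric(attr(miou, "per_class")),
    aggregation = list(dice = "global", iou = "macro",
                       prf = "micro one-vs-rest",
                       accuracy = "voxel match fraction",
                       empty_union_iou = "counted as 1"),
    n_voxels = cc$n_voxels,
    counts = cc),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", x$n_voxels, " voxels):\n", sep = "")
  for (m in c("accuracy", "mean_iou", "dice_coef", "precision",
              "sensitivity", "specificity"))
    cat(sprintf("  %-12s %.6f\n", m, x[[m]]))
  cat("  per-class IoU:", paste(sprintf("%.4f", x$per_class_iou),
                                collapse = " "), "\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A [metrics_report()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  .write_json(report[c("accuracy", "mean_iou", "dice_coef", "precision",
                       "sensitivity", "specificity", "per_class_iou",
                       "aggregation", "n_voxels")], path)
  invisible(path)
}
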