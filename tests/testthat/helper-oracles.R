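# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different primitives (logical set operations,
# explicit loops) than the package code paths they verify.

# six segmentation metrics by explicit per-class set arithmetic
oracle_metrics <- function(pred, truth, n_classes) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  n <- length(pred)
  ious <- numeric(n_classes)
  tp <- fp <- fn <- tn <- 0
  for (c in 0:(n_classes - 1L)) {
    A <- pred == c
    B <- truth == c
    inter <- sum(A & B)
    uni <- sum(A | B)
    ious[c + 1L] <- if (uni == 0) 1 else inter / uni
    tp <- tp + inter
    fp <- fp + sum(A & !B)
    fn <- fn + sum(!A & B)
    tn <- tn + (n - inter - sum(A & !B) - sum(!A & B))
  }
  list(accuracy = sum(pred == truth) / n,
       mean_iou = mean(ious),
       dice_coef = 2 * sum(pred == truth) / (2 * n),
       precision = tp / (tp + fp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       per_class_iou = ious)
}

# early stopping re-derived from the stated rule: best epoch is the
# first global argmin; stop once `patience` epochs elapsed since it
oracle_early_stop <- function(losses, patience) {
  b <- which(losses == min(losses))[1L]
  since <- length(losses) - b
  list(stop = if (patience > 0L) since >= patience else since >= 1L,
       best_epoch = b)
}

# exhaustive index-scan bounding box (0-based half-open)
oracle_bbox <- function(slice, threshold = 0) {
  idx <- which(slice > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(x1 = min(idx[, 1L]) - 1L, x2 = max(idx[, 1L]),
       y1 = min(idx[, 2L]) - 1L, y2 = max(idx[, 2L]))
}
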