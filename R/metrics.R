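check_mask_pair <- function(y, yhat, binary = TRUE) {
  if (!all(dim(y) == dim(yhat)) || length(y) != length(yhat))
    stop("mask shapes differ")
  if (binary && (!all(y %in% c(0, 1)) || !all(yhat %in% c(0, 1))))
    stop("masks must be binary {0, 1}")
}

#' Dice similarity coefficient
#'
#' `Dice = 2 |y intersect yhat| / (|y| + |yhat|)` between two binary masks.
#' When both masks are empty the ratio is 0/0 and the score is defined as
#' 1.0 (two empty segmentations agree perfectly); this convention is
#' documented rather than epsilon-smoothed.
#'
#' @param y,yhat binary masks of identical shape, values in `{0, 1}`.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(y, yhat) {
  check_mask_pair(y, yhat)
  denom <- sum(y) + sum(yhat)
  if (denom == 0) return(1)
  2 * sum(y * yhat) / denom
}

#' Intersection over union (Jaccard index)
#'
#' `IoU = |y intersect yhat| / (|y| + |yhat| - |y intersect yhat| + eps)`,
#' with a small additive constant in the denominator for numerical
#' stability. Related to Dice by `IoU = D / (2 - D)` and always
#' `IoU <= Dice`.
#'
#' @param y,yhat binary masks of identical shape.
#' @param epsilon_stab stability constant added to the union (default 1e-7).
#' @return IoU in `[0, 1]`.
#' @export
iou_score <- function(y, yhat, epsilon_stab = 1e-7) {
  check_mask_pair(y, yhat)
  inter <- sum(y * yhat)
  inter / (sum(y) + sum(yhat) - inter + epsilon_stab)
}

#' Pixel accuracy
#'
#' Fraction of pixels whose predicted label equals the ground truth:
#' `sum([y_i == yhat_i]) / N`.
#'
#' @param y,yhat masks of identical shape.
#' @return Accuracy in `[0, 1]`.
#' @export
pixel_accuracy <- function(y, yhat) {
  check_mask_pair(y, yhat, binary = FALSE)
  mean(y == yhat)
}

#' Classification report: confusion matrix and per-class metrics
#'
#' Builds the K x K confusion matrix (rows = true class, columns =
#' predicted class), overall accuracy as `correct / total * 100`, and
#' per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic
#' mean F1, and one-vs-rest accuracy. A class with an undefined metric
#' (zero denominator) is reported as 0 with a warning.
#'
#' @param truths integer true labels in `[0, K-1]`.
#' @param preds integer predicted labels, same length.
#' @param num_classes number of classes K.
#' @param class_names optional class display names.
#' @return A `classification_report`: list with `confusion` (matrix),
#'   `per_class` (tibble: `class`, `precision`, `recall`, `f1`,
#'   `ovr_accuracy`, each in `[0, 1]`), `overall_accuracy` (percent), `n`.
#' @export
classification_report <- function(truths, preds, num_classes,
                                  class_names = NULL) {
  if (length(truths) != length(preds))
    stop("truths and preds must have equal length")
  if (!length(truths)) stop("empty prediction set")
  truths <- as.integer(truths)
  preds <- as.integer(preds)
  K <- as.integer(num_classes)
  if (any(c(truths, preds) < 0L) || any(c(truths, preds) >= K))
    stop("labels must lie in [0, K-1]")
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  conf <- matrix(0L, K, K, dimnames = list(truth = class_names,
                                           predicted = class_names))
  for (i in seq_along(truths))
    conf[truths[i] + 1L, preds[i] + 1L] <- conf[truths[i] + 1L, preds[i] + 1L] + 1L
  n <- length(truths)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(class_names[den == 0], collapse = ", "),
              "; reported as 0")
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  per_class <- tibble::tibble(
    class = class_names,
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    ovr_accuracy = as.numeric((tp + tn) / n)
  )
  structure(list(confusion = conf, per_class = per_class,
                 overall_accuracy = sum(tp) / n * 100, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> n =", x$n,
      " overall accuracy =", sprintf("%.2f%%", x$overall_accuracy), "\n")
  print(x$confusion)
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], function(v) sprintf("%.1f%%", 100 * v))
  print(pc)
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$overall_accuracy,
                 macro_f1 = mean(x$per_class$f1),
                 n = x$n)
}

#' Score a set of segmentation predictions
#'
#' Computes Dice, IoU and pixel accuracy for each predicted/true mask pair
#' and returns one tidy row per pair.
#'
#' @param truths list of binary masks.
#' @param preds list of predicted binary masks, same length and shapes.
#' @param ids optional identifiers (recycled names).
#' @return Tibble with columns `id`, `dice`, `iou`, `pixel_accuracy`.
#' @export
segmentation_scores <- function(truths, preds, ids = NULL) {
  if (length(truths) != length(preds)) stop("list lengths differ")
  if (is.null(ids)) ids <- as.character(seq_along(truths))
  tibble::tibble(
    id = ids,
    dice = mapply(dice_score, truths, preds),
    iou = mapply(iou_score, truths, preds),
    pixel_accuracy = mapply(pixel_accuracy, truths, preds)
  )
}
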