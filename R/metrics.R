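## Evaluation: confusion counts over binary masks and the overlap metrics
## IoU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), PA = (TP+TN)/total.

#' Pixel confusion counts between predicted and reference masks
#'
#' Class 1 is the foreground (nucleus). Inputs must have identical shape and
#' labels in {0, 1}.
#'
#' @param pred,truth Integer matrices with values 0/1.
#' @return Object of class `confusion_counts` with fields TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("pred and truth shapes differ")
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("masks must contain only labels 0 and 1")
  }
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Overlap and accuracy metrics from confusion counts
#'
#' When TP = FP = FN = 0 (empty union) IoU and Dice are defined as 1.
#'
#' @param counts A `confusion_counts` object or a list with TP, FP, FN, TN.
#' @return Object of class `metrics_record` with IoU, Dice and PA in `[0,1]`.
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$TP
  fp <- counts$FP
  fn <- counts$FN
  tn <- counts$TN
  total <- tp + fp + fn + tn
  stopifnot(total > 0)
  if (tp + fp + fn == 0) {
    iou <- 1
    dice <- 1
  } else {
    iou <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(list(IoU = iou, Dice = dice, PA = (tp + tn) / total),
            class = "metrics_record")
}

add_counts <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 FN = a$FN + b$FN, TN = a$TN + b$TN),
            class = "confusion_counts")
}

#' Evaluate a model over a set of scenes
#'
#' @param model A `nucseg_model`.
#' @param samples List of samples, each with `$image` (H, W, 3 array) and
#'   `$mask` (H x W 0/1 matrix).
#' @param average `"micro"` pools counts over all images before computing the
#'   metrics; `"macro"` averages per-image metrics.
#' @return A `metrics_record`.
#' @export
evaluate_model <- function(model, samples, average = c("micro", "macro")) {
  average <- match.arg(average)
  if (average == "micro") {
    tot <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                     class = "confusion_counts")
    for (s in samples) {
      tot <- add_counts(tot, confusion_counts(predict_mask(model, s$image),
                                              s$mask))
    }
    segmentation_metrics(tot)
  } else {
    ms <- lapply(samples, function(s) {
      segmentation_metrics(confusion_counts(predict_mask(model, s$image),
                                            s$mask))
    })
    structure(list(IoU = mean(vapply(ms, `[[`, 0, "IoU")),
                   Dice = mean(vapply(ms, `[[`, 0, "Dice")),
                   PA = mean(vapply(ms, `[[`, 0, "PA"))),
              class = "metrics_record")
  }
}
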