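## Training loss: weighted cross-entropy + soft Dice. The default weighting
## (CE 1 : Dice 3) emphasises overlap, which matters under the extreme
## foreground scarcity of clustered nuclei imagery.

#' Loss weights for the combined objective
#'
#' @param ce_weight,dice_weight Non-negative weights; the default ratio is 3
#'   in favour of the Dice term.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(ce_weight = 1, dice_weight = 3) {
  stopifnot(ce_weight >= 0, dice_weight >= 0)
  if (ce_weight == 0 && dice_weight == 0) {
    stop("at least one loss weight must be positive")
  }
  structure(list(ce_weight = ce_weight, dice_weight = dice_weight),
            class = "loss_weights")
}

# node-level loss used by the training loop; logits: N x num_classes node,
# target: integer vector in {0, 1}
combined_loss_node <- function(logits, target, w, eps = 1) {
  parts <- NULL
  if (w$ce_weight > 0) {
    parts <- ad_smul(ad_cross_entropy(logits, target), w$ce_weight)
  }
  if (w$dice_weight > 0) {
    pfg <- ad_slice_cols(ad_softmax_rows(logits), 2L)
    dice <- ad_smul(ad_dice_loss(pfg, target, eps), w$dice_weight)
    parts <- if (is.null(parts)) dice else ad_add(parts, dice)
  }
  parts
}

#' Combined cross-entropy + soft-Dice loss
#'
#' `loss = ce_weight * CE + dice_weight * (1 - (2 sum(p t) + eps) /
#' (sum(p) + sum(t) + eps))` with `p` the softmax foreground probability and
#' `eps = 1`.
#'
#' @param logits Array c(num_classes, H, W) of class scores.
#' @param truth Integer matrix c(H, W) with values 0/1.
#' @param w A [loss_weights()] object.
#' @param eps Dice smoothing constant.
#' @return Scalar loss value.
#' @export
combined_loss <- function(logits, truth, w = loss_weights(), eps = 1) {
  stopifnot(length(dim(logits)) == 3L,
            all(dim(logits)[2:3] == dim(truth)))
  lg <- fm_to_mat(logits)
  tg <- as.integer(t(truth))  # row-major token order
  node <- combined_loss_node(ad_const(lg), tg, w, eps)
  as.numeric(node$value)
}
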