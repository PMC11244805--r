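## Gradient-weighted class activation maps: the foreground-class score is
## backpropagated to a chosen layer's activations, the spatially averaged
## gradient weights each channel, the weighted activations are rectified and
## the maximum-value channel is selected, min-max normalized and upsampled.

#' Gradient-weighted attention map for the foreground class
#'
#' Backpropagates the summed foreground-class logit to the target layer,
#' weights that layer's 2D activations by their spatially averaged gradient,
#' rectifies, selects the maximum-value channel, min-max normalizes to
#' `[0, 1]` and bilinearly upsamples to the image size.
#'
#' The default target is the decoder's fused convolutional feature map (the
#' last convolutional layer before the classifier, the usual Grad-CAM
#' choice); backbone stages 1-4 can be selected instead, though their
#' normalized transformer activations carry dense background structure and
#' localize less sharply.
#'
#' @param model A `nucseg_model`.
#' @param image Array c(H, W, 3) in `[0, 1]`.
#' @param target_layer `"decoder"` or a backbone stage index 1-4.
#' @return Numeric matrix c(H, W) in `[0, 1]` (all zeros if the gradient
#'   vanishes everywhere).
#' @export
gradcam_map <- function(model, image, target_layer = "decoder") {
  stopifnot(inherits(model, "nucseg_model"))
  if (!(identical(target_layer, "decoder") || target_layer %in% 1:4)) {
    stop("target_layer must be \"decoder\" or a stage index 1-4")
  }
  H <- dim(image)[1]
  W <- dim(image)[2]
  params <- model_params(model)
  ad_tape_start()
  on.exit({
    ad_tape_stop()
    ad_zero_grad(params)
  })
  out <- forward_tokens(model, ad_const(image_to_tokens(image)), H, W)
  score <- ad_sum(ad_slice_cols(out$logits, 2L))
  ad_backward(score)
  st <- if (identical(target_layer, "decoder")) out$fused else
    out$stages[[target_layer]]
  A <- st$t$value
  dA <- st$t$grad
  if (is.null(dA) || all(dA == 0)) {
    return(matrix(0, H, W))
  }
  wts <- colMeans(dA)
  M <- sweep(A, 2L, wts, "*")
  M[M < 0] <- 0
  ch <- which.max(apply(M, 2L, max))
  map <- M[, ch]
  rng <- range(map)
  if (rng[2] > rng[1]) {
    map <- (map - rng[1]) / (rng[2] - rng[1])
  } else {
    map <- map * 0
  }
  up <- bilinear_resize_fwd_cpp(matrix(map, ncol = 1L), st$H, st$W, H, W)
  tokens_to_map(up[, 1L], H, W)
}
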