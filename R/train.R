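## SGD training loop with the reference protocol: batch 2, SGD with
## lr 0.001, momentum 0.9, weight decay 0.0005, combined CE+Dice loss
## (ratio 3), paired flip/rotate/crop augmentation, fully seeded.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 2, SGD, learning rate
#' 0.001, momentum 0.9, weight decay 0.0005, crop 224.
#'
#' @param batch_size Images per SGD step.
#' @param lr Learning rate (constant schedule).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay folded into the gradient.
#' @param iters Number of SGD steps.
#' @param crop_size Augmentation crop side; `NULL` disables cropping.
#' @param augment Apply random flips/rotations (and crop) during training?
#' @param ce_weight,dice_weight Loss weights (see [loss_weights()]).
#' @param eval_every Evaluate on validation data every this many iterations
#'   (0 = never).
#' @param seed Integer seed controlling init, data order and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 2L, lr = 0.001, momentum = 0.9,
                         weight_decay = 5e-4, iters = 200L, crop_size = 224L,
                         augment = TRUE, ce_weight = 1, dice_weight = 3,
                         eval_every = 0L, seed = 0L) {
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 iters = as.integer(iters),
                 crop_size = if (is.null(crop_size)) NULL else
                   as.integer(crop_size),
                 augment = isTRUE(augment), ce_weight = ce_weight,
                 dice_weight = dice_weight,
                 eval_every = as.integer(eval_every), seed = as.integer(seed)),
            class = "train_config")
}

sgd_step <- function(params, state, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    v <- state[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[nm]] <- v
    p$value <- p$value - lr * v
  }
  state
}

prepare_sample <- function(s, cfg) {
  if (cfg$augment) {
    a <- random_augment(s$image, s$mask, crop_size = cfg$crop_size)
    s$image <- a$image
    s$mask <- a$mask
  } else if (!is.null(cfg$crop_size) &&
             any(dim(s$mask) != cfg$crop_size)) {
    H <- dim(s$mask)[1]
    if (cfg$crop_size > H) stop("crop size exceeds image size")
    s$image <- s$image[1:cfg$crop_size, 1:cfg$crop_size, , drop = FALSE]
    s$mask <- s$mask[1:cfg$crop_size, 1:cfg$crop_size, drop = FALSE]
  }
  s
}

#' Train a segmentation model
#'
#' Runs seeded SGD over in-memory samples (or a manifest loaded with
#' [load_manifest()]), recording the loss at every iteration and validation
#' metrics every `eval_every` iterations. Aborts with a diagnostic naming
#' the iteration if the loss becomes non-finite.
#'
#' @param model_cfg A [model_config()].
#' @param data List of samples (`$image`, `$mask`) or a manifest data frame
#'   with `image`/`mask` path columns.
#' @param cfg A [train_config()].
#' @param val_data Optional validation samples for periodic evaluation.
#' @param model Optionally continue training an existing model.
#' @return Object of class `nucseg_fit`: list with `model`, `history` (data
#'   frame of iteration, loss and metrics), `cfg`, `model_cfg`.
#' @export
train_model <- function(model_cfg, data, cfg = train_config(),
                        val_data = NULL, model = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.data.frame(data)) data <- manifest_samples(data)
  if (length(data) == 0) stop("training data is empty")
  set.seed(cfg$seed)
  if (is.null(model)) model <- build_model(model_cfg)
  params <- model_params(model)
  state <- list()
  w <- loss_weights(cfg$ce_weight, cfg$dice_weight)
  losses <- numeric(cfg$iters)
  evals <- list()
  for (it in seq_len(cfg$iters)) {
    idx <- sample.int(length(data), cfg$batch_size,
                      replace = length(data) < cfg$batch_size)
    ad_tape_start()
    loss <- NULL
    for (i in idx) {
      s <- prepare_sample(data[[i]], cfg)
      H <- dim(s$mask)[1]
      W <- dim(s$mask)[2]
      out <- forward_tokens(model, ad_const(image_to_tokens(s$image)), H, W)
      li <- combined_loss_node(out$logits, as.integer(t(s$mask)), w)
      loss <- if (is.null(loss)) li else ad_add(loss, li)
    }
    loss <- ad_smul(loss, 1 / cfg$batch_size)
    lv <- as.numeric(loss$value)
    if (!is.finite(lv)) {
      ad_tape_stop()
      stop(sprintf("training aborted: loss became non-finite at iteration %d",
                   it))
    }
    ad_backward(loss)
    ad_tape_stop()
    state <- sgd_step(params, state, cfg$lr, cfg$momentum, cfg$weight_decay)
    ad_zero_grad(params)
    losses[it] <- lv
    if (cfg$eval_every > 0 && !is.null(val_data) &&
        it %% cfg$eval_every == 0) {
      m <- evaluate_model(model, val_data)
      evals[[length(evals) + 1L]] <- data.frame(iteration = it, IoU = m$IoU,
                                                Dice = m$Dice, PA = m$PA)
    }
  }
  history <- data.frame(iteration = seq_len(cfg$iters), loss = losses)
  metrics <- if (length(evals)) do.call(rbind, evals) else NULL
  structure(list(model = model, history = history, metrics = metrics,
                 cfg = cfg, model_cfg = model_cfg),
            class = "nucseg_fit")
}

#' Save / load a model checkpoint
#'
#' A single serialized archive holding all parameter values plus a config
#' fingerprint that is verified on load.
#'
#' @param model A `nucseg_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- model_params(model)
  values <- lapply(params, function(p) p$value)
  cfg <- unclass(model$cfg)
  saveRDS(list(values = values, cfg = cfg,
               fingerprint = config_fingerprint(model$cfg)), path)
  invisible(path)
}

config_fingerprint <- function(cfg) {
  paste(vapply(unclass(cfg), function(v) paste(v, collapse = ","),
               character(1)), collapse = "|")
}

#' @rdname save_checkpoint
#' @param strict Error (rather than warn) on fingerprint mismatch.
#' @return For `load_checkpoint`, a rebuilt `nucseg_model`.
#' @export
load_checkpoint <- function(path, strict = TRUE) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, c(list(preset = ck$cfg$preset),
                                 ck$cfg[setdiff(names(ck$cfg), "preset")]))
  if (!identical(config_fingerprint(cfg), ck$fingerprint)) {
    msg <- "checkpoint fingerprint does not match its configuration"
    if (strict) stop(msg) else warning(msg)
  }
  model <- build_model(cfg)
  params <- model_params(model)
  stopifnot(identical(sort(names(params)), sort(names(ck$values))))
  for (nm in names(params)) params[[nm]]$value <- ck$values[[nm]]
  model
}
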