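## Readers/writers for paired image/mask PNGs, manifests, and the YAML run
## configuration.

#' Write an RGB image / a label mask as 8-bit PNG
#'
#' Masks are written with pixel value = class index (0 background,
#' 1 nucleus).
#'
#' @param image Array c(H, W, 3) in `[0, 1]`.
#' @param mask Integer matrix with values 0/1.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(mask / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a paired image and mask
#'
#' The image is returned as RGB reals in `[0, 1]`; the mask must be a
#' single-channel PNG with values in {0, 1} (the common 0/255 dialect is
#' mapped to 0/1 with a warning). Shape mismatch or an RGB mask is an error.
#'
#' @param image_path,mask_path PNG files.
#' @return List with `image` (H, W, 3) and `mask` (H x W integer 0/1).
#' @export
read_pair <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) == 3L) {
    stop("mask must be single-channel; got an RGB/RGBA mask: ", mask_path)
  }
  vals <- round(msk * 255)
  uv <- sort(unique(as.vector(vals)))
  if (all(uv %in% c(0, 1))) {
    mask <- matrix(as.integer(vals), nrow(vals), ncol(vals))
  } else if (all(uv %in% c(0, 255))) {
    warning("mask uses the 0/255 dialect; mapping 255 -> 1: ", mask_path)
    mask <- matrix(as.integer(vals == 255), nrow(vals), ncol(vals))
  } else {
    stop("mask values must be {0,1} (or the 0/255 dialect); got: ",
         paste(utils::head(uv), collapse = ", "))
  }
  if (!all(dim(img)[1:2] == dim(mask))) {
    stop("image and mask shapes differ: ", image_path)
  }
  list(image = img, mask = mask)
}

#' Load a dataset manifest and verify the referenced files exist
#'
#' @param path A `manifest.csv` (as written by [generate_dataset()]) or a
#'   directory containing one.
#' @return Data frame with at least `image` and `mask` columns.
#' @export
load_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(mf))) {
    stop("manifest must have image and mask columns")
  }
  missing <- c(mf$image[!file.exists(mf$image)],
               mf$mask[!file.exists(mf$mask)])
  if (length(missing)) {
    stop("manifest references missing files, e.g. ", missing[1])
  }
  if ("split" %in% names(mf)) {
    tab <- table(mf$image)
    if (any(tab > 1)) stop("splits must be disjoint over images")
  }
  mf
}

manifest_samples <- function(mf) {
  lapply(seq_len(nrow(mf)), function(i) read_pair(mf$image[i], mf$mask[i]))
}

config_defaults <- function() {
  list(preset = "tiny", batch_size = 2L, lr = 0.001, momentum = 0.9,
       weight_decay = 5e-4, iters = 200L, crop_size = 224L, augment = TRUE,
       ce_weight = 1, dice_weight = 3, eval_every = 0L, seed = 0L,
       data = NULL, outdir = "runs", num_classes = 2L)
}

#' Load a YAML run configuration
#'
#' Missing keys are filled with the protocol defaults (batch size 2, SGD
#' with lr 0.001, momentum 0.9, weight decay 0.0005, crop 224, CE:Dice
#' weight ratio 1:3); unknown keys are rejected with the field named.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return Object of class `run_config` (a named list).
#' @export
load_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(raw)] <- raw
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg$iters <- as.integer(cfg$iters)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$preset %in% c("tiny", "paperlike")) {
    stop("unknown model preset: ", cfg$preset)
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}

run_config_to_train <- function(cfg) {
  train_config(batch_size = cfg$batch_size, lr = cfg$lr,
               momentum = cfg$momentum, weight_decay = cfg$weight_decay,
               iters = cfg$iters, crop_size = cfg$crop_size,
               augment = cfg$augment, ce_weight = cfg$ce_weight,
               dice_weight = cfg$dice_weight, eval_every = cfg$eval_every,
               seed = cfg$seed)
}
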