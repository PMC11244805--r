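## Full network assembly: MREL stems, windowed-attention blocks (stages 1-2),
## APAB blocks (stages 3-4), and a UperNet-style decoder (PPM on the coarsest
## map, FPN top-down fusion) with a 1x1 classifier and bilinear upsampling.

#' Model configuration
#'
#' @param preset `"tiny"` (CPU-scale: depths 1,1,2,1, dims 16,32,64,128,
#'   window 4, decoder 64) or `"paperlike"` (depths 2,2,6,2, dims
#'   96,192,384,768, window 7, decoder 256).
#' @param ... Named overrides of any config field (`depths`, `dims`, `heads`,
#'   `window`, `groups`, `decoder_width`, `num_classes`, `stem_sizes`,
#'   `stem_stride`, `mlp_ratio`, `input_size`, `crop_size`).
#' @return Object of class `model_config`.
#' @export
model_config <- function(preset = c("tiny", "paperlike"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") {
    list(preset = "tiny", depths = c(1L, 1L, 2L, 1L),
         dims = c(16L, 32L, 64L, 128L), heads = c(1L, 2L), window = 4L,
         groups = 4L, decoder_width = 64L, num_classes = 2L,
         stem_sizes = c(4L, 8L, 16L, 32L), stem_stride = 4L, mlp_ratio = 4,
         input_size = 512L, crop_size = 224L)
  } else {
    list(preset = "paperlike", depths = c(2L, 2L, 6L, 2L),
         dims = c(96L, 192L, 384L, 768L), heads = c(3L, 6L), window = 7L,
         groups = 4L, decoder_width = 256L, num_classes = 2L,
         stem_sizes = c(4L, 8L, 16L, 32L), stem_stride = 4L, mlp_ratio = 4,
         input_size = 512L, crop_size = 224L)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown model config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(length(cfg$depths) == 4L, length(cfg$dims) == 4L,
            cfg$num_classes >= 2L,
            cfg$dims[3] %% cfg$groups == 0, cfg$dims[4] %% cfg$groups == 0)
  structure(cfg, class = "model_config")
}

#' Load a model configuration from a YAML preset
#'
#' Reads one of the shipped presets (`tiny.yaml`, `paperlike.yaml` under
#' `inst/presets/`) or any YAML file with the same fields.
#'
#' @param name Preset name (`"tiny"`, `"paperlike"`) or a path to a YAML
#'   file.
#' @return A [model_config()].
#' @export
load_model_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "nucseg")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown model preset: ", name)
  }
  y <- yaml::read_yaml(path)
  preset <- y$preset
  y$preset <- NULL
  ints <- c("depths", "dims", "heads", "window", "groups", "decoder_width",
            "num_classes", "stem_sizes", "stem_stride", "input_size",
            "crop_size")
  for (f in intersect(ints, names(y))) y[[f]] <- as.integer(y[[f]])
  do.call(model_config, c(list(preset = preset), y))
}

#' Build a segmentation model from a configuration
#'
#' Consumes the current RNG stream for weight initialization; seed the RNG
#' before calling for reproducible builds.
#'
#' @param cfg A [model_config()].
#' @return Object of class `nucseg_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$dims
  stem <- mrel_params(3L, kernel_spec(cfg$stem_sizes, cfg$stem_stride, d[1]))
  mk_attn_stage <- function(dim, depth, heads) {
    lapply(seq_len(depth), function(i) {
      shift <- if (i %% 2 == 0) cfg$window %/% 2L else 0L
      layer_block_attn(dim, heads, cfg$window, shift, cfg$mlp_ratio)
    })
  }
  mk_apab_stage <- function(dim, depth) {
    lapply(seq_len(depth), function(i) {
      layer_apab(dim, cfg$groups, cfg$mlp_ratio)
    })
  }
  stage1 <- mk_attn_stage(d[1], cfg$depths[1], cfg$heads[1])
  red12 <- stage_reduce_params(d[1], d[2])
  stage2 <- mk_attn_stage(d[2], cfg$depths[2], cfg$heads[2])
  red23 <- stage_reduce_params(d[2], d[3])
  stage3 <- mk_apab_stage(d[3], cfg$depths[3])
  red34 <- stage_reduce_params(d[3], d[4])
  stage4 <- mk_apab_stage(d[4], cfg$depths[4])
  wd <- cfg$decoder_width
  ppm_scales <- c(1L, 2L, 3L, 6L)
  ppm_proj <- lapply(ppm_scales, function(s) layer_linear(d[4], wd))
  ppm_fuse <- layer_conv(d[4] + 4L * wd, wd, 3L, pad = 1L, relu = TRUE,
                         norm = TRUE)
  laterals <- lapply(1:3, function(i) layer_linear(d[i], wd))
  smooth <- lapply(1:3, function(i) layer_conv(wd, wd, 3L, pad = 1L,
                                               relu = TRUE, norm = TRUE))
  fpn_fuse_conv <- layer_conv(4L * wd, wd, 3L, pad = 1L, relu = TRUE,
                              norm = TRUE)
  classifier <- layer_linear(wd, cfg$num_classes)
  model <- structure(
    list(cfg = cfg, stem = stem, stage1 = stage1, red12 = red12,
         stage2 = stage2, red23 = red23, stage3 = stage3, red34 = red34,
         stage4 = stage4,
         decoder = list(ppm_scales = ppm_scales, ppm_proj = ppm_proj,
                        ppm_fuse = ppm_fuse, laterals = laterals,
                        smooth = smooth, fpn_fuse = fpn_fuse_conv,
                        classifier = classifier)),
    class = "nucseg_model")
  model
}

model_params <- function(model) {
  collect_params(list(stem = model$stem, stage1 = model$stage1,
                      red12 = model$red12, stage2 = model$stage2,
                      red23 = model$red23, stage3 = model$stage3,
                      red34 = model$red34, stage4 = model$stage4,
                      decoder = model$decoder))
}

# Pyramid pooling on the coarsest feature map: adaptive average pooling at
# scales (1,2,3,6), 1x1 projection + ReLU, bilinear upsample back, concat
# with the input, fuse with a 3x3 conv to decoder width.
ppm_forward <- function(dec, x, H, W) {
  pooled <- lapply(seq_along(dec$ppm_scales), function(i) {
    s <- dec$ppm_scales[i]
    p <- ad_adaptive_avgpool(x, H, W, s, s)
    p <- ad_relu(dec$ppm_proj[[i]]$forward(p))
    ad_bilinear_resize(p, s, s, H, W)
  })
  cat_in <- ad_concat_cols(c(list(x), pooled))
  dec$ppm_fuse$forward(cat_in, H, W)$t
}

# FPN top-down pathway over the four stage features (coarsest already PPM-
# fused): lateral projection, upsample-and-add, 3x3 smoothing, upsample all
# to the finest grid, concat, fuse to decoder width.
fpn_forward <- function(dec, feats) {
  f4 <- feats[[4]]
  p <- vector("list", 4L)
  p[[4]] <- f4
  for (i in 3:1) {
    fi <- feats[[i]]
    lat <- dec$laterals[[i]]$forward(fi$t)
    up <- ad_bilinear_resize(p[[i + 1]]$t, p[[i + 1]]$H, p[[i + 1]]$W,
                             fi$H, fi$W)
    added <- ad_add(lat, up)
    sm <- dec$smooth[[i]]$forward(added, fi$H, fi$W)$t
    p[[i]] <- list(t = sm, H = fi$H, W = fi$W)
  }
  fine <- p[[1]]
  ups <- lapply(1:4, function(i) {
    if (i == 1) return(p[[i]]$t)
    ad_bilinear_resize(p[[i]]$t, p[[i]]$H, p[[i]]$W, fine$H, fine$W)
  })
  fused <- dec$fpn_fuse$forward(ad_concat_cols(ups), fine$H, fine$W)$t
  list(t = fused, H = fine$H, W = fine$W)
}

# Internal forward over autodiff nodes. Returns logits node (tokens x classes
# at full input resolution) plus per-stage feature nodes.
forward_tokens <- function(model, x, H, W) {
  cfg <- model$cfg
  f <- mrel_forward(model$stem, x, H, W)
  for (blk in model$stage1) f$t <- blk$forward(f$t, f$H, f$W)
  s1 <- f
  f <- mrel_forward(model$red12, f$t, f$H, f$W)
  for (blk in model$stage2) f$t <- blk$forward(f$t, f$H, f$W)
  s2 <- f
  f <- mrel_forward(model$red23, f$t, f$H, f$W)
  for (blk in model$stage3) f$t <- blk$forward(f$t, f$H, f$W)
  s3 <- f
  f <- mrel_forward(model$red34, f$t, f$H, f$W)
  for (blk in model$stage4) f$t <- blk$forward(f$t, f$H, f$W)
  s4 <- f
  dec <- model$decoder
  ppm_out <- ppm_forward(dec, s4$t, s4$H, s4$W)
  fused <- fpn_forward(dec, list(s1, s2, s3,
                                 list(t = ppm_out, H = s4$H, W = s4$W)))
  logits <- dec$classifier$forward(fused$t)
  logits_full <- ad_bilinear_resize(logits, fused$H, fused$W, H, W)
  list(logits = logits_full, stages = list(s1, s2, s3, s4), fused = fused)
}

# N x C tokens from an (H, W, 3) image array in [0, 1]
image_to_tokens <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  matrix(aperm(image, c(2, 1, 3)), ncol = 3L)
}

tokens_to_map <- function(v, H, W) {
  t(matrix(v, W, H))
}

#' Run the model on one image
#'
#' @param model A [build_model()] result.
#' @param image Numeric array c(H, W, 3) in `[0, 1]`; H and W must be
#'   divisible by 32 (stride-4 stem times three stride-2 reductions).
#' @param with_stages Also return the per-stage feature maps as arrays?
#' @return A list with `logits` (array c(num_classes, H, W)) and, if
#'   requested, `stages` (list of four c(C, Hs, Ws) arrays).
#' @export
model_forward <- function(model, image, with_stages = FALSE) {
  stopifnot(inherits(model, "nucseg_model"))
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (H %% 32 != 0 || W %% 32 != 0) {
    stop(sprintf("input %dx%d not divisible by 32 (stem stride 4 x three stage reductions of 2)",
                 H, W))
  }
  out <- forward_tokens(model, ad_const(image_to_tokens(image)), H, W)
  res <- list(logits = mat_to_fm(out$logits$value, H, W))
  if (with_stages) {
    res$stages <- lapply(out$stages, function(s) mat_to_fm(s$t$value, s$H, s$W))
  }
  res
}

#' Predict a segmentation mask (argmax over classes)
#'
#' @inheritParams model_forward
#' @return Integer matrix c(H, W) of class labels (0 = background).
#' @export
predict_mask <- function(model, image) {
  lg <- model_forward(model, image)$logits
  cls <- apply(lg, c(2, 3), which.max) - 1L
  matrix(as.integer(cls), dim(lg)[2], dim(lg)[3])
}

#' Count learnable scalars of a model or configuration
#'
#' @param x A `nucseg_model` or `model_config` (built temporarily; the count
#'   does not depend on the RNG).
#' @return Integer count of learnable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "model_config")) {
    seed_keep <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep,
                                            .GlobalEnv))
    x <- build_model(x)
  }
  stopifnot(inherits(x, "nucseg_model"))
  sum(vapply(model_params(x), function(p) length(p$value), numeric(1)))
}
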