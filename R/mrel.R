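## Multi-Receptive Embedding Layers: same-centre multi-kernel patch sampling
## with inverse-size dimension allocation (stage 1) and 2-kernel stride-2
## reduction layers (stages 2-4).

#' Kernel specification for a multi-receptive embedding layer
#'
#' @param sizes Strictly increasing square kernel side lengths; all branches
#'   share one stride so token counts match across branches.
#' @param stride Positive stride shared by all branches.
#' @param D Total embedding dimension after concatenation.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(sizes, stride, D) {
  stopifnot(length(sizes) >= 1, all(diff(sizes) > 0), stride >= 1, D >= 1)
  structure(list(sizes = as.integer(sizes), stride = as.integer(stride),
                 D = as.integer(D)), class = "kernel_spec")
}

#' Allocate embedding dimensions across kernel sizes
#'
#' Larger kernels cost more per dimension (conv cost scales with K^2 D^2), so
#' smaller kernels receive more dimensions: geometric halving from the
#' smallest kernel (D/2, D/4, ...) with the last two kernels sharing the tail
#' equally. For two kernels the split is 2D/3 rounded to the nearest multiple
#' of the head width (4), remainder to the larger kernel.
#'
#' @param D Total dimension.
#' @param sizes Kernel sizes (ascending); only their count matters here.
#' @param unit Rounding unit for the 2-kernel rule.
#' @return Object of class `dim_allocation` with fields `dims` and `sizes`.
#' @examples
#' allocate_dims(128, c(4, 8, 16, 32))$dims  # 64 32 16 16
#' allocate_dims(96, c(2, 4))$dims           # 64 32
#' @export
allocate_dims <- function(D, sizes, unit = 4L) {
  n <- length(sizes)
  stopifnot(n >= 1, all(diff(sizes) > 0), D >= 1)
  if (n == 1L) {
    dims <- D
  } else if (n == 2L) {
    if (D %% unit != 0 || D < 2 * unit) {
      stop(sprintf("D = %d cannot be split with the 2:1 rule: D must be a multiple of %d and at least %d",
                   D, unit, 2 * unit))
    }
    d1 <- round(2 * D / 3 / unit) * unit
    d1 <- min(max(d1, unit), D - unit)
    dims <- c(d1, D - d1)
  } else {
    if (D %% 2^(n - 1) != 0) {
      stop(sprintf("D = %d is indivisible for %d kernels: D must be a multiple of %d",
                   D, n, 2^(n - 1)))
    }
    head <- D / 2^seq_len(n - 2)
    tail_share <- (D - sum(head)) / 2
    dims <- c(head, tail_share, tail_share)
  }
  dims <- as.integer(dims)
  stopifnot(sum(dims) == D, all(dims > 0), all(diff(dims) <= 0))
  structure(list(dims = dims, sizes = as.integer(sizes)),
            class = "dim_allocation")
}

mrel_branch_pad <- function(size, stride) {
  if ((size - stride) %% 2 != 0) {
    stop(sprintf("kernel %d with stride %d needs odd one-sided padding; same-centre sampling requires (size - stride) even",
                 size, stride))
  }
  as.integer((size - stride) / 2)
}

#' Create parameters for a multi-kernel embedding layer
#'
#' One strided convolution per kernel size with same-centre padding
#' `(size - stride) / 2` on each side, so every branch produces the same
#' token grid; branch outputs are concatenated to `spec$D` channels.
#'
#' @param in_channels Input channel count (3 for an RGB image).
#' @param spec A [kernel_spec()].
#' @param alloc A [allocate_dims()] result (defaults to the halving rule).
#' @return Object of class `mrel_params`.
#' @export
mrel_params <- function(in_channels, spec,
                        alloc = allocate_dims(spec$D, spec$sizes)) {
  stopifnot(inherits(spec, "kernel_spec"), inherits(alloc, "dim_allocation"),
            length(alloc$dims) == length(spec$sizes))
  branches <- vector("list", length(spec$sizes))
  for (i in seq_along(spec$sizes)) {
    k <- spec$sizes[i]
    pad <- mrel_branch_pad(k, spec$stride)
    branches[[i]] <- layer_conv(in_channels, alloc$dims[i], k,
                                stride = spec$stride, pad = pad)
  }
  structure(list(spec = spec, alloc = alloc, branches = branches,
                 in_channels = as.integer(in_channels)),
            class = "mrel_params")
}

#' Apply a multi-kernel embedding layer to an image or feature map
#'
#' @param input Array of dim c(C, H, W) (or c(H, W, C) for an RGB image,
#'   detected by a trailing dimension of `in_channels`).
#' @param params A [mrel_params()] object.
#' @return Feature map array c(D, H/stride, W/stride).
#' @export
multi_kernel_embed <- function(input, params) {
  stopifnot(inherits(params, "mrel_params"))
  if (length(dim(input)) == 3L && dim(input)[3] == params$in_channels &&
      dim(input)[1] != params$in_channels) {
    input <- aperm(input, c(3, 1, 2))
  }
  stopifnot(dim(input)[1] == params$in_channels)
  H <- dim(input)[2]
  W <- dim(input)[3]
  if (H %% params$spec$stride != 0 || W %% params$spec$stride != 0) {
    stop("input spatial dims must be divisible by the stride")
  }
  x <- ad_const(fm_to_mat(input))
  out <- mrel_forward(params, x, H, W)
  mat_to_fm(out$t$value, out$H, out$W)
}

mrel_forward <- function(params, x, H, W) {
  outs <- lapply(params$branches, function(b) b$forward(x, H, W))
  list(t = ad_concat_cols(lapply(outs, function(o) o$t)),
       H = outs[[1]]$H, W = outs[[1]]$W)
}

#' Create parameters for a stage-reduction embedding layer
#'
#' Two same-centre branches (2x2 and 4x4 kernels, both stride 2) concatenated
#' to `D_out` channels; the token count drops to one fourth.
#'
#' @param in_channels Input channels.
#' @param D_out Output channels.
#' @return Object of class `stage_reduce_params`.
#' @export
stage_reduce_params <- function(in_channels, D_out) {
  spec <- kernel_spec(c(2L, 4L), 2L, D_out)
  mrel_params(in_channels, spec)
}

#' Apply a stage-reduction layer
#'
#' @param input Feature map array c(C, H, W) with even H and W.
#' @param params A [stage_reduce_params()] object (created on the fly from
#'   `D_out` if a bare integer is supplied).
#' @return Feature map array c(D_out, H/2, W/2).
#' @export
stage_reduce <- function(input, params) {
  if (is.numeric(params)) {
    params <- stage_reduce_params(dim(input)[1], as.integer(params))
  }
  H <- dim(input)[2]
  W <- dim(input)[3]
  if (H %% 2 != 0 || W %% 2 != 0) {
    stop("stage reduction requires even spatial dims")
  }
  multi_kernel_embed(input, params)
}
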