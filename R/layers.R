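## Neural layers built on the autodiff engine. A layer is a list holding its
## parameter tensors (and sub-layers) plus a $forward closure. Feature maps
## travel between layers as lists (t = N x C token node, H, W).

trunc_normal <- function(n, std = 0.02) {
  pmin(pmax(stats::rnorm(n, 0, std), -2 * std), 2 * std)
}

layer_linear <- function(din, dout, std = 0.02) {
  W <- ad_param(matrix(trunc_normal(din * dout, std), din, dout))
  b <- ad_param(numeric(dout))
  list(kind = "linear", params = list(W = W, b = b),
       forward = function(x) ad_add_bias(ad_matmul(x, W), b))
}

layer_layernorm <- function(dim) {
  gamma <- ad_param(rep(1, dim))
  beta <- ad_param(numeric(dim))
  list(kind = "layernorm", params = list(gamma = gamma, beta = beta),
       forward = function(x) ad_layernorm(x, gamma, beta))
}

layer_mlp <- function(dim, ratio = 4) {
  fc1 <- layer_linear(dim, dim * ratio)
  fc2 <- layer_linear(dim * ratio, dim)
  list(kind = "mlp", sub = list(fc1 = fc1, fc2 = fc2),
       forward = function(x) fc2$forward(ad_gelu(fc1$forward(x))))
}

layer_conv <- function(cin, cout, k, stride = 1L, pad = 0L, relu = FALSE,
                       norm = FALSE) {
  force(cin); force(cout); force(k); force(stride); force(pad); force(relu)
  force(norm)
  fan_in <- k * k * cin
  W <- ad_param(matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                       fan_in, cout))
  b <- ad_param(numeric(cout))
  ln <- if (norm) layer_layernorm(cout)
  list(kind = "conv", params = list(W = W, b = b), k = k,
       sub = if (norm) list(ln = ln),
       forward = function(x, H, W_sp) {
         out <- ad_conv2d(x, H, W_sp, W, b, k, stride, pad)
         if (norm) out <- ln$forward(out)
         if (relu) out <- ad_relu(out)
         list(t = out, H = (H + 2 * pad - k) %/% stride + 1L,
              W = (W_sp + 2 * pad - k) %/% stride + 1L)
       })
}

## ------------------------------------------------------ window attention ----

# permutation putting tokens in (window, within-window row-major) order
win_partition_idx <- function(H, W, win) {
  idx <- integer(H * W)
  pos <- 1L
  for (wr in seq_len(H %/% win) - 1L) {
    for (wc in seq_len(W %/% win) - 1L) {
      for (r in seq_len(win) - 1L) {
        rows <- (wr * win + r) * W + wc * win + seq_len(win)
        idx[pos:(pos + win - 1L)] <- rows
        pos <- pos + win
      }
    }
  }
  idx
}

# cyclic roll by s rows and s cols: new (r, c) reads old (r + s, c + s)
roll_idx <- function(H, W, s) {
  r <- rep(0:(H - 1), each = W)
  c <- rep(0:(W - 1), times = H)
  ((r + s) %% H) * W + ((c + s) %% W) + 1L
}

# zero-pad an H x W token grid to Hp x Wp (top-left anchored)
pad_token_rows <- function(H, W, Hp, Wp) {
  unlist(lapply(0:(H - 1), function(r) r * Wp + 0:(W - 1))) + 1L
}

ad_pad_tokens <- function(x, H, W, Hp, Wp) {
  rows <- pad_token_rows(H, W, Hp, Wp)
  v <- matrix(0, Hp * Wp, ncol(x$value))
  v[rows, ] <- x$value
  ad_op(v, list(x), function(g) ad_accum(x, g[rows, , drop = FALSE]))
}

layer_wmsa <- function(dim, heads, window, shift = 0L) {
  force(window); force(shift)
  stopifnot(dim %% heads == 0)
  dh <- dim %/% heads
  qkv <- layer_linear(dim, 3L * dim)
  proj <- layer_linear(dim, dim)
  list(kind = "wmsa", sub = list(qkv = qkv, proj = proj),
       heads = heads, window = window, shift = shift,
       forward = function(x, H, W) {
         win <- window
         Hp <- ceiling(H / win) * win
         Wp <- ceiling(W / win) * win
         padded <- Hp != H || Wp != W
         if (padded) x <- ad_pad_tokens(x, H, W, Hp, Wp)
         fidx <- win_partition_idx(Hp, Wp, win)
         if (shift > 0L) {
           rl <- roll_idx(Hp, Wp, shift)
           fidx <- rl[fidx]
         }
         inv <- integer(length(fidx))
         inv[fidx] <- seq_along(fidx)
         xg <- ad_gather_rows(x, fidx)
         qkv_all <- qkv$forward(xg)
         ws <- win * win
         nwin <- (Hp * Wp) %/% ws
         wins <- vector("list", nwin)
         for (wi in seq_len(nwin)) {
           rows <- ((wi - 1L) * ws + 1L):(wi * ws)
           qw <- ad_slice_rows(qkv_all, rows)
           outs <- vector("list", heads)
           for (h in seq_len(heads)) {
             qc <- ((h - 1L) * dh + 1L):(h * dh)
             q <- ad_slice_cols(qw, qc)
             k <- ad_slice_cols(qw, dim + qc)
             v <- ad_slice_cols(qw, 2L * dim + qc)
             attn <- ad_softmax_rows(ad_smul(ad_matmul(q, k, transpose_b = TRUE),
                                             1 / sqrt(dh)))
             outs[[h]] <- ad_matmul(attn, v)
           }
           wins[[wi]] <- if (heads > 1L) ad_concat_cols(outs) else outs[[1L]]
         }
         out <- if (nwin > 1L) ad_concat_rows(wins) else wins[[1L]]
         out <- ad_gather_rows(out, inv)
         if (padded) out <- ad_slice_rows(out, pad_token_rows(H, W, Hp, Wp))
         proj$forward(out)
       })
}

layer_block_attn <- function(dim, heads, window, shift = 0L, mlp_ratio = 4) {
  force(shift)
  ln1 <- layer_layernorm(dim)
  ln2 <- layer_layernorm(dim)
  attn <- layer_wmsa(dim, heads, window, shift)
  mlp <- layer_mlp(dim, mlp_ratio)
  list(kind = "block_attn",
       sub = list(ln1 = ln1, attn = attn, ln2 = ln2, mlp = mlp),
       forward = function(x, H, W) {
         x <- ad_add(x, attn$forward(ln1$forward(x), H, W))
         ad_add(x, mlp$forward(ln2$forward(x)))
       })
}

## ------------------------------------------------------------ APAB block ----

layer_apab <- function(dim, groups = 4L, mlp_ratio = 4, pred_std = 1e-3) {
  stopifnot(dim %% groups == 0)
  Cp <- dim %/% groups
  grid <- build_sampling_grid(3L, 3L, 1L)
  K <- nrow(grid$points)
  ln1 <- layer_layernorm(dim)
  ln2 <- layer_layernorm(dim)
  # offset/modulation predictor: 3x3 depthwise + 1x1 pointwise emitting
  # 2GK offset maps and GK modulation maps; pointwise near-zero so training
  # starts arbitrarily close to the static separable-convolution limit
  dw_w <- ad_param(matrix(stats::rnorm(9 * dim, 0, sqrt(2 / 9)), 9, dim))
  dw_b <- ad_param(numeric(dim))
  pred <- layer_linear(dim, 3L * groups * K, std = pred_std)
  gamma_raw <- ad_param(matrix(0.1, 1, 1))
  # per-group point projections, identity at init (pass-through point part)
  Wg <- lapply(seq_len(groups), function(g) ad_param(diag(Cp)))
  names(Wg) <- paste0("Wg", seq_len(groups))
  out_proj <- layer_linear(dim, dim)
  mlp <- layer_mlp(dim, mlp_ratio)
  nofs <- 2L * groups * K
  list(kind = "apab", groups = groups, grid = grid,
       params = c(list(dw_w = dw_w, dw_b = dw_b, gamma_raw = gamma_raw), Wg),
       sub = list(ln1 = ln1, pred = pred, out_proj = out_proj,
                  ln2 = ln2, mlp = mlp),
       forward = function(x, H, W) {
         h <- ln1$forward(x)
         p <- pred$forward(ad_dwconv(h, H, W, dw_w, dw_b, 3L, 1L))
         raw_off <- ad_slice_cols(p, seq_len(nofs))
         raw_mod <- ad_slice_cols(p, nofs + seq_len(groups * K))
         # ROI extent = current feature map (W, H): columns alternate
         # (drow, dcol) so scale by (H, W) pairs, then by clamped gamma
         gam <- ad_clamp(gamma_raw, 0.01, 0.5)
         offs <- ad_scalar_mul(ad_colscale(raw_off, rep(c(H, W), groups * K)),
                               gam)
         mods <- ad_concat_cols(lapply(seq_len(groups), function(g) {
           ad_softmax_rows(ad_slice_cols(raw_mod, (g - 1L) * K + seq_len(K)))
         }))
         s <- ad_deform_agg(h, H, W, groups, offs, mods, grid$points)
         s <- ad_concat_cols(lapply(seq_len(groups), function(g) {
           ad_matmul(ad_slice_cols(s, (g - 1L) * Cp + seq_len(Cp)), Wg[[g]])
         }))
         s <- out_proj$forward(s)
         x <- ad_add(x, s)
         ad_add(x, mlp$forward(ln2$forward(x)))
       })
}

#' Create the parameter set of an Adaptive Pixel Adjustment block
#'
#' The block is a same-resolution residual transformer-style block whose
#' token mixer is grouped deformable aggregation: layer norm, a lightweight
#' 3x3 depthwise + 1x1 pointwise predictor emitting per-group raw offsets
#' (2GK maps) and raw modulations (GK maps), gamma/ROI offset scaling,
#' per-group softmax modulation normalization, deformable aggregation with
#' per-group point projections, an output projection, a residual add, then a
#' norm + 2-layer MLP with a second residual.
#'
#' @param dim Channel width of the block.
#' @param groups Number of aggregation groups G (default 4).
#' @param mlp_ratio Hidden expansion of the MLP.
#' @return Object of class `apab_params`.
#' @export
apab_params <- function(dim, groups = 4L, mlp_ratio = 4) {
  structure(list(layer = layer_apab(dim, groups, mlp_ratio),
                 dim = as.integer(dim), groups = as.integer(groups)),
            class = "apab_params")
}

#' Apply an Adaptive Pixel Adjustment block to a feature map
#'
#' @param x Feature map array c(C, H, W) with C equal to `params$dim`.
#' @param params An [apab_params()] object.
#' @return Feature map array of the same shape.
#' @export
apab_block <- function(x, params) {
  stopifnot(inherits(params, "apab_params"))
  if (dim(x)[1] != params$dim) {
    stop(sprintf("channel mismatch: block width is %d, input has %d channels",
                 params$dim, dim(x)[1]))
  }
  H <- dim(x)[2]
  W <- dim(x)[3]
  out <- params$layer$forward(ad_const(fm_to_mat(x)), H, W)
  mat_to_fm(out$value, H, W)
}

## ------------------------------------------------------- param collection ----

collect_params <- function(module, prefix = "") {
  out <- list()
  if (is.list(module)) {
    if (!is.null(module$params)) {
      for (nm in names(module$params)) {
        out[[paste0(prefix, nm)]] <- module$params[[nm]]
      }
    }
    if (!is.null(module$sub)) {
      for (nm in names(module$sub)) {
        out <- c(out, collect_params(module$sub[[nm]],
                                     paste0(prefix, nm, ".")))
      }
    }
    if (is.null(module$params) && is.null(module$sub) &&
        is.null(module$forward)) {
      nms <- names(module)
      if (is.null(nms)) nms <- as.character(seq_along(module))
      nms[nms == ""] <- as.character(which(nms == ""))
      for (i in seq_along(module)) {
        if (!is.list(module[[i]])) next
        out <- c(out, collect_params(module[[i]], paste0(prefix, nms[i], ".")))
      }
    }
  }
  out
}
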