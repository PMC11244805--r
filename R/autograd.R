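## Minimal tape-based reverse-mode automatic differentiation.
##
## Values are numeric matrices (tokens x channels) or plain arrays. Nodes are
## environments holding $value, $grad and a $backward closure; intermediate
## nodes are recorded on a dynamic tape in creation (topological) order, so a
## single reverse sweep over the tape propagates gradients. Parameters
## (ad_param) live off-tape and accumulate gradients across forward passes
## until ad_zero_grad() is called.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Start recording an autodiff tape
#'
#' Every differentiable operation created while a tape is active is recorded
#' so that [ad_backward()] can sweep it in reverse. Tapes are cheap; start a
#' fresh one per training step.
#' @return The tape environment, invisibly.
#' @keywords internal
#' @export
ad_tape_start <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .ad$tape <- tp
  invisible(tp)
}

#' Stop recording and discard the active tape
#' @return `NULL`, invisibly.
#' @keywords internal
#' @export
ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_record <- function(node) {
  tp <- .ad$tape
  if (is.null(tp)) return(invisible(node))
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- node
  tp$n <- n
  invisible(node)
}

#' Create a tensor node
#'
#' @param value Numeric matrix or array.
#' @param requires_grad Should gradients be accumulated into this node?
#' @return An `ad_tensor` (environment with `$value` and `$grad`).
#' @keywords internal
#' @export
ad_tensor <- function(value, requires_grad = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- requires_grad
  node$backward <- NULL
  class(node) <- "ad_tensor"
  node
}

#' Create a learnable parameter (off-tape tensor with gradients)
#' @param value Initial numeric value.
#' @return An `ad_tensor` with `requires_grad = TRUE`.
#' @keywords internal
#' @export
ad_param <- function(value) ad_tensor(value, requires_grad = TRUE)

#' Wrap a constant (no gradient) value
#' @param value Numeric value.
#' @return An `ad_tensor` with `requires_grad = FALSE`.
#' @keywords internal
#' @export
ad_const <- function(value) ad_tensor(value, requires_grad = FALSE)

ad_op <- function(value, parents, backward) {
  req <- FALSE
  for (p in parents) if (isTRUE(p$requires)) { req <- TRUE; break }
  node <- ad_tensor(value, requires_grad = req)
  if (req) {
    node$backward <- backward
    ad_record(node)
  }
  node
}

ad_accum <- function(node, g) {
  if (!isTRUE(node$requires)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Reverse sweep: propagate gradients from a scalar loss
#' @param loss Scalar `ad_tensor` produced under the active tape.
#' @return `NULL`, invisibly.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  tp <- .ad$tape
  if (is.null(tp)) stop("ad_backward() called without an active tape")
  if (length(loss$value) != 1L) stop("ad_backward() expects a scalar loss")
  loss$grad <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

#' Zero the gradients of a list of parameters
#' @param params List of `ad_tensor` parameters.
#' @return `NULL`, invisibly.
#' @keywords internal
#' @export
ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ----------------------------------------------------------- primitives ----

ad_add <- function(a, b) {
  ad_op(a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_add_bias <- function(a, b) {
  # a: N x C, b: length-C bias vector
  ad_op(sweep(a$value, 2L, b$value, "+"), list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, colSums(g))
  })
}

ad_mul <- function(a, b) {
  ad_op(a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

# multiply a tensor by a scalar tensor (e.g. the gamma amplitude)
ad_scalar_mul <- function(a, s) {
  ad_op(a$value * as.numeric(s$value), list(a, s), function(g) {
    ad_accum(a, g * as.numeric(s$value))
    ad_accum(s, sum(g * a$value))
  })
}

ad_smul <- function(a, k) {
  # constant scalar multiply
  ad_op(a$value * k, list(a), function(g) ad_accum(a, g * k))
}

ad_colscale <- function(a, w) {
  # constant per-column scale, w length ncol(a)
  ad_op(sweep(a$value, 2L, w, "*"), list(a), function(g) {
    ad_accum(a, sweep(g, 2L, w, "*"))
  })
}

ad_matmul <- function(a, b, transpose_b = FALSE) {
  v <- if (transpose_b) tcrossprod(a$value, b$value) else a$value %*% b$value
  ad_op(v, list(a, b), function(g) {
    if (transpose_b) {
      ad_accum(a, g %*% b$value)
      ad_accum(b, crossprod(g, a$value))
    } else {
      ad_accum(a, tcrossprod(g, b$value))
      ad_accum(b, crossprod(a$value, g))
    }
  })
}

ad_relu <- function(a) {
  mask <- a$value > 0
  ad_op(a$value * mask, list(a), function(g) ad_accum(a, g * mask))
}

ad_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  ad_op(x * ph, list(a), function(g) {
    ad_accum(a, g * (ph + x * stats::dnorm(x)))
  })
}

ad_softmax_rows <- function(a) {
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  ad_op(p, list(a), function(g) {
    ad_accum(a, (g - rowSums(g * p)) * p)
  })
}

ad_clamp <- function(a, lo, hi) {
  inside <- a$value >= lo & a$value <= hi
  ad_op(pmin(pmax(a$value, lo), hi), list(a), function(g) {
    ad_accum(a, g * inside)
  })
}

ad_sum <- function(a) {
  ad_op(sum(a$value), list(a), function(g) {
    gg <- a$value
    gg[] <- g
    ad_accum(a, gg)
  })
}

ad_mean <- function(a) {
  n <- length(a$value)
  ad_op(mean(a$value), list(a), function(g) {
    gg <- a$value
    gg[] <- g / n
    ad_accum(a, gg)
  })
}

ad_gather_rows <- function(a, idx) {
  # idx must be a permutation of 1:nrow(a)
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  ad_op(a$value[idx, , drop = FALSE], list(a), function(g) {
    ad_accum(a, g[inv, , drop = FALSE])
  })
}

ad_slice_rows <- function(a, rows) {
  nr <- nrow(a$value)
  ad_op(a$value[rows, , drop = FALSE], list(a), function(g) {
    dx <- matrix(0, nr, ncol(a$value))
    dx[rows, ] <- g
    ad_accum(a, dx)
  })
}

ad_slice_cols <- function(a, cols) {
  nc <- ncol(a$value)
  ad_op(a$value[, cols, drop = FALSE], list(a), function(g) {
    dx <- matrix(0, nrow(a$value), nc)
    dx[, cols] <- g
    ad_accum(a, dx)
  })
}

ad_concat_cols <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_op(do.call(cbind, vals), nodes, function(g) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_concat_rows <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_op(do.call(rbind, vals), nodes, function(g) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  v <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_op(v, list(a, gamma, beta), function(g) {
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    if (isTRUE(a$requires)) {
      dxh <- sweep(g, 2L, gamma$value, "*")
      dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / sd_
      ad_accum(a, dx)
    }
  })
}

## ------------------------------------------------------- conv wrappers ----

ad_conv2d <- function(x, H, W, weight, bias, k, stride = 1L, pad = 0L) {
  col <- im2col_cpp(x$value, H, W, k, k, stride, pad)
  v <- sweep(col %*% weight$value, 2L, bias$value, "+")
  ad_op(v, list(x, weight, bias), function(g) {
    ad_accum(weight, crossprod(col, g))
    ad_accum(bias, colSums(g))
    if (isTRUE(x$requires)) {
      dcol <- tcrossprod(g, weight$value)
      ad_accum(x, col2im_cpp(dcol, H, W, ncol(x$value), k, k, stride, pad))
    }
  })
}

ad_dwconv <- function(x, H, W, weight, bias, k, pad) {
  v <- dwconv_fwd_cpp(x$value, H, W, weight$value, bias$value, k, k, pad)
  ad_op(v, list(x, weight, bias), function(g) {
    bk <- dwconv_bwd_cpp(g, x$value, H, W, weight$value, k, k, pad)
    ad_accum(weight, bk$dw)
    ad_accum(bias, as.numeric(bk$db))
    ad_accum(x, bk$dx)
  })
}

ad_deform_agg <- function(x, H, W, G, offs, mods, grid_pts) {
  v <- deform_agg_fwd_cpp(x$value, H, W, G, offs$value, mods$value, grid_pts)
  ad_op(v, list(x, offs, mods), function(g) {
    bk <- deform_agg_bwd_cpp(g, x$value, H, W, G, offs$value, mods$value,
                             grid_pts)
    ad_accum(x, bk$dx)
    ad_accum(offs, bk$doffs)
    ad_accum(mods, bk$dmods)
  })
}

ad_bilinear_resize <- function(x, H, W, Ho, Wo) {
  v <- bilinear_resize_fwd_cpp(x$value, H, W, Ho, Wo)
  ad_op(v, list(x), function(g) {
    ad_accum(x, bilinear_resize_bwd_cpp(g, H, W, Ho, Wo, ncol(x$value)))
  })
}

# adaptive average pooling to oh x ow bins (bins may overlap when
# upsizing, matching the floor/ceil bin convention)
ad_adaptive_avgpool <- function(x, H, W, oh, ow) {
  bins <- vector("list", oh * ow)
  for (i in seq_len(oh)) {
    r0 <- floor((i - 1) * H / oh)
    r1 <- ceiling(i * H / oh) - 1
    for (j in seq_len(ow)) {
      c0 <- floor((j - 1) * W / ow)
      c1 <- ceiling(j * W / ow) - 1
      rows <- rep(r0:r1, each = c1 - c0 + 1)
      cols <- rep(c0:c1, times = r1 - r0 + 1)
      bins[[(i - 1) * ow + j]] <- rows * W + cols + 1L
    }
  }
  v <- matrix(0, oh * ow, ncol(x$value))
  for (b in seq_along(bins)) {
    v[b, ] <- colMeans(x$value[bins[[b]], , drop = FALSE])
  }
  ad_op(v, list(x), function(g) {
    dx <- matrix(0, nrow(x$value), ncol(x$value))
    for (b in seq_along(bins)) {
      idx <- bins[[b]]
      share <- g[b, ] / length(idx)
      dx[idx, ] <- dx[idx, ] + matrix(share, length(idx), length(share),
                                      byrow = TRUE)
    }
    ad_accum(x, dx)
  })
}

## --------------------------------------------------------------- losses ----

# fused softmax + cross-entropy; target is an integer vector in {0, 1, ...}
ad_cross_entropy <- function(logits, target) {
  x <- logits$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  n <- nrow(p)
  sel <- cbind(seq_len(n), target + 1L)
  v <- -mean(log(pmax(p[sel], 1e-12)))
  ad_op(v, list(logits), function(g) {
    onehot <- matrix(0, n, ncol(p))
    onehot[sel] <- 1
    ad_accum(logits, g * (p - onehot) / n)
  })
}

# soft Dice loss on foreground probabilities (column vector node)
ad_dice_loss <- function(pfg, target, eps = 1) {
  p <- as.numeric(pfg$value)
  t <- as.numeric(target)
  A <- 2 * sum(p * t) + eps
  B <- sum(p) + sum(t) + eps
  v <- 1 - A / B
  ad_op(v, list(pfg), function(g) {
    dp <- -(2 * t * B - A) / (B * B)
    ad_accum(pfg, matrix(g * dp, ncol = 1L))
  })
}
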