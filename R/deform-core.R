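## Adaptive Pixel Adjustment core: sampling grid, bilinear sampling,
## modulation normalization, gamma-scaled offsets and grouped deformable
## aggregation, plus a literal per-pixel oracle used by the tests.
##
## Conventions: feature maps are arrays of dim c(C, H, W); coordinates are
## (row, col), 0-based; offsets are (delta_row, delta_col) in continuous
## pixels at the current resolution; reads outside the map return zeros.

#' Build the fixed sampling grid of a deformable kernel
#'
#' Returns the K = `kernel_h * kernel_w` centred integer grid points of a
#' conventional convolution kernel, in fixed row-major order: a 3x3 grid is
#' (-1,-1), (-1,0), (-1,1), (0,-1), ..., (1,1), times `dilation`.
#'
#' @param kernel_h,kernel_w Odd positive kernel side lengths.
#' @param dilation Positive integer spacing between grid points.
#' @return An object of class `sampling_grid`: a list with `points` (a K x 2
#'   integer matrix of (delta_row, delta_col)), `kernel_h`, `kernel_w`,
#'   `dilation`.
#' @examples
#' build_sampling_grid(3, 3)$points
#' @export
build_sampling_grid <- function(kernel_h, kernel_w, dilation = 1L) {
  stopifnot(kernel_h >= 1, kernel_w >= 1, dilation >= 1)
  if (kernel_h %% 2 == 0 || kernel_w %% 2 == 0) {
    stop("kernel sides must be odd: a centred grid is undefined for even sizes")
  }
  rh <- (kernel_h - 1L) %/% 2L
  rw <- (kernel_w - 1L) %/% 2L
  pts <- as.matrix(expand.grid(dc = (-rw:rw) * dilation,
                               dr = (-rh:rh) * dilation))[, c("dr", "dc")]
  pts <- matrix(as.integer(pts), ncol = 2L,
                dimnames = list(NULL, c("drow", "dcol")))
  structure(list(points = pts, kernel_h = as.integer(kernel_h),
                 kernel_w = as.integer(kernel_w),
                 dilation = as.integer(dilation)),
            class = "sampling_grid")
}

#' Bilinearly sample a feature map at a fractional position
#'
#' Interpolates the four integer neighbours of `point`; positions outside
#' `[0, H-1] x [0, W-1]` contribute zero (zero-padding contract), so any real
#' position is valid.
#'
#' @param fm Array of dim c(C, H, W) (a matrix is treated as 1 x H x W).
#' @param point Numeric 2-vector (row, col), 0-based, possibly fractional.
#' @return Numeric C-vector of interpolated channel values.
#' @export
bilinear_sample <- function(fm, point) {
  if (is.matrix(fm)) fm <- array(fm, c(1L, nrow(fm), ncol(fm)))
  stopifnot(length(dim(fm)) == 3L, length(point) == 2L, all(is.finite(fm)))
  H <- dim(fm)[2]
  W <- dim(fm)[3]
  r <- point[1]
  cc <- point[2]
  r0 <- floor(r)
  c0 <- floor(cc)
  fr <- r - r0
  fc <- cc - c0
  out <- numeric(dim(fm)[1])
  for (dr in 0:1) {
    rr <- r0 + dr
    if (rr < 0 || rr > H - 1) next
    wr <- if (dr == 1) fr else 1 - fr
    if (wr == 0) next
    for (dc in 0:1) {
      ccc <- c0 + dc
      if (ccc < 0 || ccc > W - 1) next
      w <- wr * (if (dc == 1) fc else 1 - fc)
      if (w != 0) out <- out + w * fm[, rr + 1, ccc + 1]
    }
  }
  out
}

#' Normalize raw modulation scores to sum to one over the grid points
#'
#' Softmax along the K axis, computed in the max-shifted log-sum-exp form and
#' then exponentiated, so the K scalars of every (group, position) sum to 1.
#'
#' @param raw Numeric array of dim c(G, K, H, W), a matrix with K columns
#'   (positions x K), or a plain K-vector.
#' @return Same shape as `raw`, non-negative, summing to 1 over the K axis.
#' @export
normalize_modulation <- function(raw) {
  stopifnot(all(is.finite(raw)))
  softmax_lse <- function(m) {
    # rows of m are independent; softmax over columns
    mx <- apply(m, 1L, max)
    lse <- mx + log(rowSums(exp(m - mx)))
    exp(m - lse)
  }
  if (is.null(dim(raw))) {
    return(as.numeric(softmax_lse(matrix(raw, nrow = 1L))))
  }
  if (is.matrix(raw)) return(softmax_lse(raw))
  stopifnot(length(dim(raw)) == 4L)
  d <- dim(raw)
  # move K last, flatten all other axes to rows
  flat <- matrix(aperm(raw, c(1, 3, 4, 2)), ncol = d[2])
  out <- softmax_lse(flat)
  aperm(array(out, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

#' Learnable clamped offset-amplitude scale
#'
#' The deformation amplitude gamma is a learnable scalar hard-clamped to
#' `[0.01, 0.5]`, initialized at 0.1. The effective value multiplies predicted
#' offsets together with the ROI extent, bounding how far sampling points can
#' reach.
#'
#' @param raw Unconstrained real parameter value.
#' @return Object of class `gamma_scale` with fields `raw` and `effective`.
#' @export
gamma_scale <- function(raw = 0.1) {
  structure(list(raw = raw, effective = min(max(raw, 0.01), 0.5)),
            class = "gamma_scale")
}

#' Scale raw predicted offsets by gamma and the ROI extent
#'
#' Applies `delta_p = gamma * delta_p_hat (x) (w, h)` element-wise: the
#' horizontal (col) component is multiplied by `gamma * w`, the vertical
#' (row) component by `gamma * h`.
#'
#' @param raw_offsets Array of dim c(G, K, 2, H, W); third axis is
#'   (delta_row, delta_col).
#' @param gamma A `gamma_scale` object (or a bare numeric, clamped likewise).
#' @param roi List or numeric with positive extents `w` (horizontal) and `h`
#'   (vertical).
#' @return Array with the same shape as `raw_offsets`.
#' @export
scale_offsets <- function(raw_offsets, gamma, roi) {
  if (is.numeric(gamma)) gamma <- gamma_scale(gamma)
  w <- if (is.list(roi)) roi$w else roi[[1]]
  h <- if (is.list(roi)) roi$h else roi[[2]]
  if (!is.numeric(w) || !is.numeric(h) || w <= 0 || h <= 0) {
    stop("roi extents (w, h) must be positive")
  }
  stopifnot(length(dim(raw_offsets)) == 5L, dim(raw_offsets)[3] == 2L)
  out <- raw_offsets
  out[, , 1, , ] <- gamma$effective * h * raw_offsets[, , 1, , ]
  out[, , 2, , ] <- gamma$effective * w * raw_offsets[, , 2, , ]
  out
}

#' Per-group point projection weights
#'
#' The shared "point part" of the separable weight: one `C' x C'` projection
#' matrix per group, with `C' = C / G` (C must divide exactly). Default is
#' the identity in every group.
#'
#' @param G Number of groups (default 4).
#' @param C Total channel count.
#' @param point_weights Optional array of dim c(C', C', G).
#' @return Object of class `group_projection`.
#' @export
group_projection <- function(G, C, point_weights = NULL) {
  stopifnot(G >= 1, C >= 1)
  if (C %% G != 0) stop("C must be divisible by G (C' = C/G exactly)")
  Cp <- C %/% G
  if (is.null(point_weights)) {
    point_weights <- array(0, c(Cp, Cp, G))
    for (g in seq_len(G)) point_weights[, , g] <- diag(Cp)
  }
  stopifnot(all(dim(point_weights) == c(Cp, Cp, G)))
  structure(list(G = as.integer(G), C = as.integer(C), Cp = as.integer(Cp),
                 point_weights = point_weights),
            class = "group_projection")
}

# array (G,K,2,H,W) -> matrix N x (2GK), column (g*K + k)*2 + d (0-based)
offsets_to_mat <- function(offsets) {
  d <- dim(offsets)
  t(matrix(aperm(offsets, c(3, 2, 1, 5, 4)), nrow = d[3] * d[2] * d[1]))
}

# array (G,K,H,W) -> matrix N x (GK), column g*K + k (0-based)
mods_to_mat <- function(mods) {
  d <- dim(mods)
  t(matrix(aperm(mods, c(2, 1, 4, 3)), nrow = d[2] * d[1]))
}

fm_to_mat <- function(fm) {
  d <- dim(fm)
  t(matrix(aperm(fm, c(1, 3, 2)), nrow = d[1]))
}

mat_to_fm <- function(X, H, W) {
  C <- ncol(X)
  aperm(array(t(X), c(C, W, H)), c(1, 3, 2))
}

check_agg_shapes <- function(x, proj, offsets, mods, grid) {
  dx <- dim(x)
  K <- nrow(grid$points)
  if (dx[1] %% proj$G != 0 || dx[1] != proj$C) {
    stop("channel count of x must equal proj$C and divide by proj$G")
  }
  if (!all(dim(offsets) == c(proj$G, K, 2L, dx[2], dx[3]))) {
    stop("offsets shape mismatch: expected (G, K, 2, H, W)")
  }
  if (!all(dim(mods) == c(proj$G, K, dx[2], dx[3]))) {
    stop("mods shape mismatch: expected (G, K, H, W)")
  }
  if (!all(is.finite(offsets))) stop("offsets must be finite")
  sums <- apply(mods, c(1, 3, 4), sum)
  if (max(abs(sums - 1)) > 1e-5) {
    stop("mods must be normalized: sum over K must equal 1 per (group, position)")
  }
  invisible(K)
}

apply_group_projection <- function(S, proj) {
  out <- S
  for (g in seq_len(proj$G)) {
    cols <- ((g - 1) * proj$Cp + 1):(g * proj$Cp)
    out[, cols] <- S[, cols, drop = FALSE] %*% proj$point_weights[, , g]
  }
  out
}

#' Grouped adaptive deformable aggregation
#'
#' For each output position p0 and group g, samples the g-th channel slice at
#' the K grid points displaced by that group's continuous offsets, weights
#' the samples by the normalized modulation scalars, sums over the grid, and
#' applies the group's point projection; group outputs are concatenated along
#' channels. Sampling is bilinear with zero padding.
#'
#' @param x Feature map array of dim c(C, H, W).
#' @param proj A [group_projection()].
#' @param offsets Array c(G, K, 2, H, W) of (delta_row, delta_col) offsets.
#' @param mods Array c(G, K, H, W), normalized over K (see
#'   [normalize_modulation()]).
#' @param grid A [build_sampling_grid()] result.
#' @return Feature map array c(C, H, W).
#' @export
adaptive_aggregate <- function(x, proj, offsets, mods, grid) {
  check_agg_shapes(x, proj, offsets, mods, grid)
  X <- fm_to_mat(x)
  S <- deform_agg_fwd_cpp(X, dim(x)[2], dim(x)[3], proj$G,
                          offsets_to_mat(offsets), mods_to_mat(mods),
                          grid$points)
  mat_to_fm(apply_group_projection(S, proj), dim(x)[2], dim(x)[3])
}

#' Literal nested-loop oracle for the grouped aggregation
#'
#' Evaluates the aggregation one scalar sample at a time with
#' [bilinear_sample()]; by construction this is the definition that
#' [adaptive_aggregate()] must reproduce. Intended for small instances only.
#'
#' @inheritParams adaptive_aggregate
#' @return Feature map array c(C, H, W).
#' @export
brute_force_aggregate <- function(x, proj, offsets, mods, grid) {
  check_agg_shapes(x, proj, offsets, mods, grid)
  d <- dim(x)
  H <- d[2]
  W <- d[3]
  K <- nrow(grid$points)
  Cp <- proj$Cp
  y <- array(0, d)
  for (r in 0:(H - 1)) {
    for (cc in 0:(W - 1)) {
      for (g in seq_len(proj$G)) {
        ch <- ((g - 1) * Cp + 1):(g * Cp)
        slice <- x[ch, , , drop = FALSE]
        acc <- numeric(Cp)
        for (k in seq_len(K)) {
          p <- c(r + grid$points[k, 1] + offsets[g, k, 1, r + 1, cc + 1],
                 cc + grid$points[k, 2] + offsets[g, k, 2, r + 1, cc + 1])
          acc <- acc + mods[g, k, r + 1, cc + 1] * bilinear_sample(slice, p)
        }
        y[ch, r + 1, cc + 1] <- t(proj$point_weights[, , g]) %*% acc
      }
    }
  }
  y
}
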