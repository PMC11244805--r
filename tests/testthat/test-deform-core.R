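test_that("sampling grid is centred, row-major and dilation-scaled", {
  g <- build_sampling_grid(3, 3, 1)
  expect_equal(unname(g$points),
               matrix(c(-1, -1, -1, 0, -1, 1,
                        0, -1, 0, 0, 0, 1,
                        1, -1, 1, 0, 1, 1),
                      ncol = 2, byrow = TRUE))
  expect_equal(unname(build_sampling_grid(1, 1, 1)$points),
               matrix(c(0L, 0L), 1))
  g2 <- build_sampling_grid(3, 3, 2)
  expect_true(all(g2$points %in% c(-2L, 0L, 2L)))
  expect_equal(nrow(g2$points), 9L)
  expect_error(build_sampling_grid(2, 3, 1), "odd")
  expect_error(build_sampling_grid(3, 4, 1), "odd")
})

test_that("bilinear sampling interpolates with a zero-padding border", {
  set.seed(7)
  fm <- array(rnorm(3 * 5 * 6), c(3, 5, 6))
  # integer lattice points are exact reads
  expect_equal(bilinear_sample(fm, c(2, 3)), fm[, 3, 4])
  # equal-weight midpoint of a 2x2 map
  sq <- array(0, c(1, 2, 2))
  sq[1, 1, 1] <- 1; sq[1, 1, 2] <- 3; sq[1, 2, 1] <- 5; sq[1, 2, 2] <- 7
  expect_equal(bilinear_sample(sq, c(0.5, 0.5)), 4)
  # far outside: all zeros
  expect_equal(bilinear_sample(fm, c(-5, -5)), rep(0, 3))
  # partially outside: remaining corners only
  expect_equal(bilinear_sample(sq, c(-0.5, 0)), 0.5 * 1)
})

test_that("modulation normalization is a shift-invariant softmax over K", {
  expect_equal(normalize_modulation(rep(1.3, 9)), rep(1 / 9, 9))
  expect_equal(normalize_modulation(c(0, log(3))), c(0.25, 0.75))
  set.seed(1)
  x <- rnorm(9)
  expect_equal(normalize_modulation(x), normalize_modulation(x + 17.3))
  # per-(group, position) sums over the K axis are 1 to 1e-6
  raw <- array(rnorm(3 * 9 * 4 * 5, sd = 4), c(3, 9, 4, 5))
  m <- normalize_modulation(raw)
  sums <- apply(m, c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(m >= 0))
})

test_that("offset scaling applies the clamped gamma and ROI extents", {
  raw <- array(0, c(1, 1, 2, 1, 1))
  raw[1, 1, , 1, 1] <- c(1, 1)  # (drow, dcol)
  out <- scale_offsets(raw, gamma_scale(0.1), list(w = 10, h = 6))
  expect_equal(out[1, 1, 2, 1, 1], 1.0)  # dcol scales by gamma * w
  expect_equal(out[1, 1, 1, 1, 1], 0.6)  # drow scales by gamma * h
  # clamp: raw gamma 0.7 -> effective 0.5
  expect_equal(gamma_scale(0.7)$effective, 0.5)
  expect_equal(gamma_scale(-2)$effective, 0.01)
  # fresh initialization -> effective 0.1
  expect_equal(gamma_scale()$effective, 0.1)
  expect_error(scale_offsets(raw, gamma_scale(0.1), list(w = -1, h = 6)),
               "positive")
  # bound: |dp| <= 0.5 * |raw| * extent component-wise, 0.1 at default init
  set.seed(2)
  r2 <- array(rnorm(2 * 9 * 2 * 3 * 3), c(2, 9, 2, 3, 3))
  sc <- scale_offsets(r2, gamma_scale(123), list(w = 8, h = 8))
  expect_true(all(abs(sc) <= 0.5 * abs(r2) * 8 + 1e-12))
  sc0 <- scale_offsets(r2, gamma_scale(), list(w = 8, h = 8))
  expect_true(all(abs(sc0) <= 0.1 * abs(r2) * 8 + 1e-12))
})

test_that("identity configuration reproduces the input exactly", {
  set.seed(3)
  x <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  g <- build_sampling_grid(1, 1, 1)
  y <- adaptive_aggregate(x, group_projection(1, 6),
                          array(0, c(1, 1, 2, 4, 4)),
                          array(1, c(1, 1, 4, 4)), g)
  expect_equal(y, x)
  # centre one-hot modulation on a 3x3 grid also selects p0 itself
  g3 <- build_sampling_grid(3, 3, 1)
  mods <- array(0, c(2, 9, 4, 4))
  mods[, 5, , ] <- 1
  y2 <- adaptive_aggregate(x, group_projection(2, 6),
                           array(0, c(2, 9, 2, 4, 4)), mods, g3)
  expect_equal(y2, x)
  y3 <- brute_force_aggregate(x, group_projection(2, 6),
                              array(0, c(2, 9, 2, 4, 4)), mods, g3)
  expect_equal(y3, x)
})

test_that("zero offsets with uniform modulation reduce to a box filter", {
  set.seed(4)
  C <- 2; H <- 6; W <- 5
  x <- array(rnorm(C * H * W), c(C, H, W))
  g <- build_sampling_grid(3, 3, 1)
  y <- adaptive_aggregate(x, group_projection(1, C),
                          array(0, c(1, 9, 2, H, W)),
                          array(1 / 9, c(1, 9, H, W)), g)
  # oracle: direct zero-padded 3x3 mean filter
  box <- array(0, dim(x))
  for (ch in 1:C) for (r in 1:H) for (cc in 1:W) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) acc <- acc + x[ch, rr, c2]
    }
    box[ch, r, cc] <- acc / 9
  }
  expect_equal(y, box, tolerance = 1e-12)
})

test_that("vectorized aggregation matches the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    G <- sample(c(1, 2), 1)
    C <- G * sample(2:3, 1)
    H <- sample(4:6, 1); W <- sample(4:6, 1)
    g <- build_sampling_grid(3, 3, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    offs <- array(runif(G * 9 * 2 * H * W, -1, 1), c(G, 9, 2, H, W))
    mods <- rand_mods(G, 9, H, W)
    proj <- group_projection(G, C,
                             array(rnorm((C / G)^2 * G), c(C / G, C / G, G)))
    y1 <- adaptive_aggregate(x, proj, offs, mods, g)
    y2 <- brute_force_aggregate(x, proj, offs, mods, g)
    expect_lt(max(abs(y1 - y2)), 1e-10)
  }
})

test_that("aggregation validates shapes and normalization", {
  set.seed(5)
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  g <- build_sampling_grid(3, 3, 1)
  proj <- group_projection(2, 4)
  offs <- array(0, c(2, 9, 2, 3, 3))
  mods <- rand_mods(2, 9, 3, 3)
  expect_error(adaptive_aggregate(x, proj, offs[, 1:4, , , ], mods, g),
               "offsets shape")
  expect_error(adaptive_aggregate(x, proj, offs, mods[1, , , , drop = FALSE], g),
               "mods shape")
  expect_error(adaptive_aggregate(x, proj, offs, mods * 2, g), "normalized")
  expect_error(group_projection(3, 4), "divisible")
})

test_that("APAB block keeps resolution and reduces to a static path when the predictor is zeroed", {
  set.seed(6)
  dim_ <- 8L
  ap <- apab_params(dim_, groups = 2L)
  x <- array(rnorm(dim_ * 6 * 6), c(dim_, 6, 6))
  y <- apab_block(x, ap)
  expect_equal(dim(y), dim(x))
  expect_error(apab_block(array(0, c(dim_ + 1, 6, 6)), ap), "channel mismatch")

  # force the offset/modulation predictor to zero: offsets vanish and the
  # modulation softmax of zeros is uniform, so the mixer is exactly the
  # static separable path; recompute that path independently from the
  # block's own weight matrices using the exported operators
  lay <- ap$layer
  lay$sub$pred$params$W$value[] <- 0
  lay$sub$pred$params$b$value[] <- 0
  dw_w <- lay$params$dw_w$value  # unused once pointwise is zero
  yz <- apab_block(x, ap)
  # independent recomputation: pre-norm, uniform 3x3 aggregation, group
  # point projections, output projection, residual, then the MLP branch
  ln <- function(m, gamma, beta) {
    mu <- rowMeans(m); xc <- m - mu
    sd_ <- sqrt(rowMeans(xc^2) + 1e-5)
    sweep(sweep(xc / sd_, 2, gamma, "*"), 2, beta, "+")
  }
  X <- t(matrix(aperm(x, c(1, 3, 2)), nrow = dim_))
  h <- ln(X, lay$sub$ln1$params$gamma$value, lay$sub$ln1$params$beta$value)
  harr <- aperm(array(t(h), c(dim_, 6, 6)), c(1, 3, 2))
  Wg <- array(0, c(4, 4, 2))
  Wg[, , 1] <- lay$params$Wg1$value
  Wg[, , 2] <- lay$params$Wg2$value
  s <- adaptive_aggregate(harr, group_projection(2, dim_, Wg),
                          array(0, c(2, 9, 2, 6, 6)),
                          array(1 / 9, c(2, 9, 6, 6)),
                          build_sampling_grid(3, 3, 1))
  S <- t(matrix(aperm(s, c(1, 3, 2)), nrow = dim_))
  S <- sweep(S %*% lay$sub$out_proj$params$W$value, 2,
             lay$sub$out_proj$params$b$value, "+")
  X1 <- X + S
  h2 <- ln(X1, lay$sub$ln2$params$gamma$value, lay$sub$ln2$params$beta$value)
  gelu <- function(m) m * pnorm(m)
  m1 <- gelu(sweep(h2 %*% lay$sub$mlp$sub$fc1$params$W$value, 2,
                   lay$sub$mlp$sub$fc1$params$b$value, "+"))
  m2 <- sweep(m1 %*% lay$sub$mlp$sub$fc2$params$W$value, 2,
              lay$sub$mlp$sub$fc2$params$b$value, "+")
  expected <- aperm(array(t(X1 + m2), c(dim_, 6, 6)), c(1, 3, 2))
  expect_equal(yz, expected, tolerance = 1e-10)
})

test_that("the gamma amplitude receives a finite-difference-consistent gradient", {
  set.seed(8)
  dim_ <- 8L
  ap <- apab_params(dim_, groups = 2L)
  lay <- ap$layer
  x <- matrix(rnorm(16 * dim_), 16, dim_)
  loss_at <- function(graw) {
    old <- lay$params$gamma_raw$value
    lay$params$gamma_raw$value <- matrix(graw, 1, 1)
    on.exit(lay$params$gamma_raw$value <- old)
    out <- lay$forward(nucseg:::ad_const(x), 4L, 4L)
    sum(out$value^2)
  }
  nucseg:::ad_tape_start()
  out <- lay$forward(nucseg:::ad_const(x), 4L, 4L)
  loss <- nucseg:::ad_sum(nucseg:::ad_mul(out, out))
  nucseg:::ad_backward(loss)
  nucseg:::ad_tape_stop()
  g_auto <- as.numeric(lay$params$gamma_raw$grad)
  nucseg:::ad_zero_grad(nucseg:::collect_params(lay))
  expect_true(is.finite(g_auto))
  expect_gt(abs(g_auto), 0)
  g_fd <- (loss_at(0.1 + 1e-4) - loss_at(0.1 - 1e-4)) / 2e-4
  expect_lt(abs(g_auto - g_fd) / max(abs(g_fd), 1e-8), 1e-3)
})
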