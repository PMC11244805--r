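test_that("window attention equals a dense evaluation of scaled dot-product attention", {
  set.seed(31)
  dim_ <- 8L
  lay <- nucseg:::layer_wmsa(dim_, heads = 2L, window = 2L, shift = 0L)
  x <- matrix(rnorm(4 * dim_), 4, dim_)  # one 2x2 window
  out <- lay$forward(nucseg:::ad_const(x), 2L, 2L)$value
  Wqkv <- lay$sub$qkv$params$W$value
  bqkv <- lay$sub$qkv$params$b$value
  qkv <- sweep(x %*% Wqkv, 2, bqkv, "+")
  dh <- dim_ / 2
  dense <- matrix(0, 4, dim_)
  for (h in 1:2) {
    cols <- (h - 1) * dh + seq_len(dh)
    q <- qkv[, cols]; k <- qkv[, dim_ + cols]; v <- qkv[, 2 * dim_ + cols]
    a <- q %*% t(k) / sqrt(dh)
    a <- exp(a - apply(a, 1, max)); a <- a / rowSums(a)
    dense[, cols] <- a %*% v
  }
  dense <- sweep(dense %*% lay$sub$proj$params$W$value, 2,
                 lay$sub$proj$params$b$value, "+")
  expect_equal(out, dense, tolerance = 1e-10)
})

test_that("identical keys give uniform attention and single-token windows pass V through", {
  set.seed(32)
  dim_ <- 4L
  lay <- nucseg:::layer_wmsa(dim_, heads = 1L, window = 2L, shift = 0L)
  # identical rows -> identical K rows -> uniform attention -> equal outputs
  x <- matrix(rep(rnorm(dim_), each = 4), 4, dim_)
  out <- lay$forward(nucseg:::ad_const(x), 2L, 2L)$value
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
  # window of a single token: attention over one row is that row's V
  lay1 <- nucseg:::layer_wmsa(dim_, heads = 1L, window = 1L, shift = 0L)
  x1 <- matrix(rnorm(dim_), 1, dim_)
  o1 <- lay1$forward(nucseg:::ad_const(x1), 1L, 1L)$value
  qkv <- sweep(x1 %*% lay1$sub$qkv$params$W$value, 2,
               lay1$sub$qkv$params$b$value, "+")
  v <- qkv[, 2 * dim_ + seq_len(dim_), drop = FALSE]
  expect_equal(o1, sweep(v %*% lay1$sub$proj$params$W$value, 2,
                         lay1$sub$proj$params$b$value, "+"),
               tolerance = 1e-12)
})

test_that("shifted and non-shifted window blocks differ on generic input", {
  set.seed(33)
  dim_ <- 8L
  a <- nucseg:::layer_wmsa(dim_, 2L, 2L, shift = 0L)
  b <- nucseg:::layer_wmsa(dim_, 2L, 2L, shift = 1L)
  b$sub$qkv$params$W$value <- a$sub$qkv$params$W$value
  b$sub$qkv$params$b$value <- a$sub$qkv$params$b$value
  b$sub$proj$params$W$value <- a$sub$proj$params$W$value
  b$sub$proj$params$b$value <- a$sub$proj$params$b$value
  x <- matrix(rnorm(16 * dim_), 16, dim_)
  oa <- a$forward(nucseg:::ad_const(x), 4L, 4L)$value
  ob <- b$forward(nucseg:::ad_const(x), 4L, 4L)$value
  expect_gt(max(abs(oa - ob)), 1e-6)
})

test_that("pyramid pooling keeps resolution and projects to the decoder width", {
  set.seed(34)
  cfg <- model_config("tiny")
  mdl <- build_model(cfg)
  x <- matrix(rnorm(16 * 128), 16, 128)  # a 4x4 stage-4 map
  out <- nucseg:::ppm_forward(mdl$decoder, nucseg:::ad_const(x), 4L, 4L)
  expect_equal(dim(out$value), c(16L, 64L))
  # constant input: every pooled scale is that constant
  xc <- matrix(rep(rnorm(128), each = 16), 16, 128)
  p <- nucseg:::ad_adaptive_avgpool(nucseg:::ad_const(xc), 4L, 4L, 3L, 3L)
  expect_lt(max(abs(sweep(p$value, 2, xc[1, ]))), 1e-12)
})

test_that("tiny model obeys the pyramid and logit shape contracts on 224x224", {
  set.seed(35)
  cfg <- model_config("tiny")
  mdl <- build_model(cfg)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  out <- model_forward(mdl, img, with_stages = TRUE)
  expect_equal(dim(out$logits), c(2L, 224L, 224L))
  expect_equal(lapply(out$stages, function(s) dim(s)[2:3]),
               list(c(56L, 56L), c(28L, 28L), c(14L, 14L), c(7L, 7L)))
  expect_true(all(is.finite(out$logits)))
  expect_error(model_forward(mdl, array(0, c(100, 100, 3))),
               "divisible by 32")
})

test_that("parameter counting is exact and additive", {
  # a single 2 -> 3 linear map with bias has 9 scalars
  set.seed(36)
  lin <- nucseg:::layer_linear(2, 3)
  expect_equal(sum(vapply(nucseg:::collect_params(lin),
                          function(p) length(p$value), numeric(1))), 9)
  # adding one APAB block at stage 3 adds exactly the analytic block size
  c1 <- count_parameters(model_config("tiny", depths = c(1L, 1L, 1L, 1L)))
  c2 <- count_parameters(model_config("tiny", depths = c(1L, 1L, 2L, 1L)))
  d <- 64; G <- 4; K <- 9; Cp <- d / G
  apab_scalars <- 2 * d +                     # ln1
    (9 * d + d) +                             # depthwise conv
    (d * 3 * G * K + 3 * G * K) +             # pointwise predictor
    1 +                                       # gamma
    G * Cp * Cp +                             # group point projections
    (d * d + d) +                             # output projection
    2 * d +                                   # ln2
    (d * 4 * d + 4 * d) + (4 * d * d + d)     # MLP
  expect_equal(c2 - c1, apab_scalars)
})

test_that("model building is deterministic under a fixed seed", {
  cfg <- model_config("tiny")
  set.seed(37); m1 <- build_model(cfg)
  set.seed(37); m2 <- build_model(cfg)
  p1 <- nucseg:::model_params(m1)
  p2 <- nucseg:::model_params(m2)
  expect_identical(lapply(p1, function(p) p$value),
                   lapply(p2, function(p) p$value))
})

test_that("YAML presets match the built-in configurations", {
  expect_equal(load_model_preset("tiny"), model_config("tiny"))
  expect_equal(load_model_preset("paperlike"), model_config("paperlike"))
  expect_error(load_model_preset("nope"), "unknown")
})
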