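# finite-difference validation of the reverse-mode engine on small instances

ad <- function(x) nucseg:::ad_tensor(x, requires_grad = TRUE)

# run f (builder of a scalar node from a list of ad tensors), return
# autodiff grads and compare with central differences on each input
check_grads <- function(build, values, tol = 1e-5) {
  tensors <- lapply(values, ad)
  nucseg:::ad_tape_start()
  loss <- build(tensors)
  nucseg:::ad_backward(loss)
  nucseg:::ad_tape_stop()
  for (i in seq_along(values)) {
    f_i <- function(v) {
      vals <- values
      vals[[i]] <- v
      ts <- lapply(vals, nucseg:::ad_const)
      as.numeric(build(ts)$value)
    }
    g_fd <- fd_grad(f_i, values[[i]])
    g_ad <- tensors[[i]]$grad
    expect_lt(rel_err(g_ad, g_fd), tol)
  }
}

test_that("matmul, bias, layernorm and activations backpropagate correctly", {
  set.seed(11)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(6), 3, 2)
  b <- rnorm(2)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_gelu(
      nucseg:::ad_add_bias(nucseg:::ad_matmul(t[[1]], t[[2]]), t[[3]])))
  }, list(A, B, b))
  gam <- runif(3, 0.5, 1.5)
  bet <- rnorm(3)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(
      nucseg:::ad_layernorm(t[[1]], t[[2]], t[[3]]),
      nucseg:::ad_layernorm(t[[1]], t[[2]], t[[3]])))
  }, list(A, gam, bet), tol = 1e-4)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(nucseg:::ad_softmax_rows(t[[1]]), t[[2]]))
  }, list(A, matrix(rnorm(12), 4, 3)))
})

test_that("convolution kernels backpropagate correctly", {
  set.seed(12)
  H <- 5; W <- 4; C <- 3; Co <- 2; k <- 3
  X <- matrix(rnorm(H * W * C), H * W, C)
  Wt <- matrix(rnorm(k * k * C * Co), k * k * C, Co)
  bb <- rnorm(Co)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_gelu(
      nucseg:::ad_conv2d(t[[1]], H, W, t[[2]], t[[3]], k, 1L, 1L)))
  }, list(X, Wt, bb), tol = 1e-4)
  # strided, padded
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(
      nucseg:::ad_conv2d(t[[1]], H, W, t[[2]], t[[3]], k, 2L, 1L),
      nucseg:::ad_conv2d(t[[1]], H, W, t[[2]], t[[3]], k, 2L, 1L)))
  }, list(X, Wt, bb), tol = 1e-4)
  Wd <- matrix(rnorm(9 * C), 9, C)
  bd <- rnorm(C)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_gelu(
      nucseg:::ad_dwconv(t[[1]], H, W, t[[2]], t[[3]], 3L, 1L)))
  }, list(X, Wd, bd), tol = 1e-4)
})

test_that("deformable aggregation gradients agree with finite differences", {
  set.seed(13)
  H <- 4; W <- 4; G <- 2; C <- 4; K <- 9
  grid <- build_sampling_grid(3, 3, 1)$points
  X <- matrix(rnorm(H * W * C), H * W, C)
  offs <- matrix(runif(H * W * 2 * G * K, -1, 1), H * W, 2 * G * K)
  mods <- matrix(runif(H * W * G * K, 0.05, 1), H * W, G * K)
  wexp <- matrix(rnorm(H * W * C), H * W, C)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(
      nucseg:::ad_deform_agg(t[[1]], H, W, G, t[[2]], t[[3]], grid),
      nucseg:::ad_const(wexp)))
  }, list(X, offs, mods), tol = 1e-3)
})

test_that("resize, pooling, gather/slice/pad and clamp backpropagate", {
  set.seed(14)
  H <- 4; W <- 5; C <- 2
  X <- matrix(rnorm(H * W * C), H * W, C)
  wexp <- matrix(rnorm(8 * 10 * C), 80, C)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(
      nucseg:::ad_bilinear_resize(t[[1]], H, W, 8L, 10L),
      nucseg:::ad_const(wexp)))
  }, list(X), tol = 1e-4)
  wp <- matrix(rnorm(6 * C), 6, C)
  check_grads(function(t) {
    nucseg:::ad_sum(nucseg:::ad_mul(
      nucseg:::ad_adaptive_avgpool(t[[1]], H, W, 2L, 3L),
      nucseg:::ad_const(wp)))
  }, list(X), tol = 1e-4)
  perm <- sample(H * W)
  check_grads(function(t) {
    g <- nucseg:::ad_gather_rows(t[[1]], perm)
    s <- nucseg:::ad_slice_cols(g, 2L)
    nucseg:::ad_sum(nucseg:::ad_mul(s, s))
  }, list(X), tol = 1e-4)
  check_grads(function(t) {
    p <- nucseg:::ad_pad_tokens(t[[1]], H, W, 6L, 6L)
    nucseg:::ad_sum(nucseg:::ad_mul(p, p))
  }, list(X), tol = 1e-4)
  # clamp passes gradient only strictly inside the box
  v <- matrix(c(-0.5, 0.2, 0.7), 1)
  tv <- ad(v)
  nucseg:::ad_tape_start()
  loss <- nucseg:::ad_sum(nucseg:::ad_clamp(tv, 0.01, 0.5))
  nucseg:::ad_backward(loss)
  nucseg:::ad_tape_stop()
  expect_equal(as.numeric(tv$grad), c(0, 1, 0))
})

test_that("loss nodes backpropagate correctly", {
  set.seed(15)
  n <- 12
  logits <- matrix(rnorm(2 * n), n, 2)
  target <- sample(0:1, n, replace = TRUE)
  check_grads(function(t) {
    nucseg:::ad_cross_entropy(t[[1]], target)
  }, list(logits), tol = 1e-4)
  check_grads(function(t) {
    p <- nucseg:::ad_slice_cols(nucseg:::ad_softmax_rows(t[[1]]), 2L)
    nucseg:::ad_dice_loss(p, target)
  }, list(logits), tol = 1e-4)
})
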