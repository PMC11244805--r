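# shared test utilities: finite-difference gradients and small random fields

# central-difference gradient of scalar-valued f at every entry of x
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# random normalized modulation field (G, K, H, W)
rand_mods <- function(G, K, H, W) {
  normalize_modulation(array(stats::rnorm(G * K * H * W), c(G, K, H, W)))
}

rand_scene_samples <- function(n, spec = scene_spec(), seed0 = 0L) {
  lapply(seq_len(n), function(i) {
    s <- generate_scene(spec, seed0 + i - 1L)
    list(image = s$image, mask = s$mask)
  })
}

# environment shared across acceptance blocks (micro-trained model cache)
.acc <- new.env(parent = emptyenv())
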