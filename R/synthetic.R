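## Deterministic generator of nuclei-like scenes: clustered, overlapping
## ellipses with rough (radially perturbed) boundaries, darker stain than a
## textured background, and a target foreground-fraction band enforced by
## rejection resampling. Stands in for clustered cervical cytology imagery
## so the whole pipeline is testable without any download.

#' Scene specification for the synthetic nuclei generator
#'
#' @param size Square image side in pixels.
#' @param count Integer range c(lo, hi) of nuclei per scene.
#' @param radius Range of mean nucleus radii in pixels (>= 2).
#' @param cluster_tightness Spread of nuclei around their cluster centre, as
#'   a fraction of `size`.
#' @param overlap_prob Probability that a nucleus is placed adjacent to an
#'   existing one so that their masks intersect (adherent pair).
#' @param roughness Amplitude of the radial boundary perturbation (a
#'   truncated 8-harmonic Fourier series with amplitudes proportional to
#'   `roughness / harmonic`).
#' @param fg_band Target foreground-fraction band (subset of (0, 1));
#'   scenes are resampled until the rendered fraction falls inside.
#' @param noise Additive Gaussian pixel noise sd.
#' @param texture Amplitude of the smooth background texture.
#' @param stain Mean RGB colour of the nucleus stain (darker than `bg`).
#' @param bg Mean RGB colour of the background.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(size = 64L, count = c(1L, 4L), radius = c(2.5, 6),
                       cluster_tightness = 0.12, overlap_prob = 0.3,
                       roughness = 0.15, fg_band = c(0.02, 0.06),
                       noise = 0.02, texture = 0.04,
                       stain = c(0.36, 0.24, 0.55),
                       bg = c(0.86, 0.80, 0.88)) {
  stopifnot(size >= 16, length(count) == 2, count[1] >= 1,
            count[2] >= count[1], length(radius) == 2, radius[1] >= 2,
            radius[2] >= radius[1], overlap_prob >= 0, overlap_prob <= 1,
            roughness >= 0, length(fg_band) == 2,
            fg_band[1] > 0, fg_band[2] < 1, fg_band[2] > fg_band[1])
  spec <- structure(list(size = as.integer(size), count = as.integer(count),
                         radius = radius,
                         cluster_tightness = cluster_tightness,
                         overlap_prob = overlap_prob, roughness = roughness,
                         fg_band = fg_band, noise = noise, texture = texture,
                         stain = stain, bg = bg),
                    class = "scene_spec")
  # feasibility: the band must be reachable with the allowed count/radii
  amax <- count[2] * pi * (radius[2] * (1 + roughness))^2 / size^2
  amin <- count[1] * pi * (radius[1] * 0.5)^2 / size^2
  if (amax < fg_band[1] || amin > fg_band[2]) {
    stop(sprintf("foreground band (%.5f, %.5f) is infeasible for size %d with %d-%d nuclei of radius %.1f-%.1f",
                 fg_band[1], fg_band[2], size, count[1], count[2],
                 radius[1], radius[2]))
  }
  spec
}

#' Extreme-scarcity scene specification
#'
#' Large scenes in which only about 0.01% of pixels are nucleus, mirroring
#' the foreground scarcity of clustered cervical cytology slides; intended
#' for class-imbalance stress tests rather than CPU training.
#'
#' @param size Image side (default 1024).
#' @return A [scene_spec()].
#' @export
scene_spec_scarce <- function(size = 1024L) {
  scene_spec(size = size, count = c(1L, 2L), radius = c(3, 6),
             fg_band = c(5e-5, 2e-4), overlap_prob = 0.5)
}

# render one nucleus into a size x size logical mask; pixel centres at
# integer 0-based (row, col); boundary: rho(theta) <= 1 + sum_h a_h cos(h
# theta + phi_h) in ellipse-normalized coordinates
render_nucleus <- function(size, row, col, a, b, rot, amps, phases) {
  reach <- max(a, b) * (1 + sum(amps)) + 1
  r0 <- max(0, floor(row - reach))
  r1 <- min(size - 1, ceiling(row + reach))
  c0 <- max(0, floor(col - reach))
  c1 <- min(size - 1, ceiling(col + reach))
  m <- matrix(FALSE, size, size)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1
  cc <- c0:c1
  y <- matrix(rr - row, length(rr), length(cc))
  x <- matrix(cc - col, length(rr), length(cc), byrow = TRUE)
  xr <- x * cos(rot) + y * sin(rot)
  yr <- -x * sin(rot) + y * cos(rot)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  theta <- atan2(yr, xr)
  f <- 1
  for (h in seq_along(amps)) f <- f + amps[h] * cos(h * theta + phases[h])
  m[rr + 1, cc + 1] <- rho <= f
  m
}

sample_nucleus_params <- function(spec, prev, clusters) {
  s <- spec$size
  r <- stats::runif(1, spec$radius[1], spec$radius[2])
  ref_idx <- NA_integer_
  if (length(prev) > 0 && stats::runif(1) < spec$overlap_prob) {
    ref_idx <- sample.int(length(prev), 1)
    ref <- prev[[ref_idx]]
    ang <- stats::runif(1, 0, 2 * pi)
    d <- stats::runif(1, 0.35, 0.65) * (ref$r + r)
    ctr <- c(ref$row + d * sin(ang), ref$col + d * cos(ang))
  } else {
    cl <- clusters[sample.int(nrow(clusters), 1), ]
    ctr <- cl + stats::rnorm(2) * spec$cluster_tightness * s
  }
  ctr <- pmin(pmax(ctr, 2), s - 3)
  aspect <- stats::runif(1, 0.6, 1)
  amps <- spec$roughness * abs(stats::rnorm(8)) / seq_len(8)
  list(row = ctr[1], col = ctr[2], r = r, a = r / sqrt(aspect),
       b = r * sqrt(aspect), rot = stats::runif(1, 0, pi), amps = amps,
       phases = stats::runif(8, 0, 2 * pi), ref = ref_idx)
}

#' Generate one synthetic nuclei scene
#'
#' Nuclei are placed by a cluster-centre + jitter process (with adherent
#' placement under `overlap_prob`), rendered as radially perturbed ellipses,
#' and the scene is resampled until the foreground fraction falls inside the
#' spec's band. The image is a textured background with darker stained
#' nuclei plus additive noise. Fully determined by `(spec, seed)`.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @param max_attempts Rejection-resampling budget.
#' @return Object of class `scene_sample`: list with `image` (size, size, 3),
#'   `mask` (0/1 integer matrix), `params` (per-nucleus table), `seed`,
#'   `spec`, and the per-nucleus masks.
#' @export
generate_scene <- function(spec, seed, max_attempts = 300L) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  s <- spec$size
  for (attempt in seq_len(max_attempts)) {
    n <- if (spec$count[1] == spec$count[2]) spec$count[1] else
      sample(spec$count[1]:spec$count[2], 1L)
    ncl <- max(1L, round(n / 3))
    clusters <- matrix(stats::runif(2 * ncl, 0.2 * s, 0.8 * s), ncl, 2)
    nuclei <- list()
    for (i in seq_len(n)) {
      nuclei[[i]] <- sample_nucleus_params(spec, nuclei, clusters)
    }
    masks <- lapply(nuclei, function(p) {
      render_nucleus(s, p$row, p$col, p$a, p$b, p$rot, p$amps, p$phases)
    })
    mask <- Reduce(`|`, masks)
    frac <- mean(mask)
    # adherent placements must actually share/touch boundary pixels
    adjacent_ok <- all(vapply(seq_along(nuclei), function(i) {
      ri <- nuclei[[i]]$ref
      if (is.na(ri)) return(TRUE)
      any(dilate_mask(masks[[i]]) & masks[[ri]])
    }, logical(1)))
    if (adjacent_ok && frac >= spec$fg_band[1] && frac <= spec$fg_band[2]) {
      image <- render_image(spec, mask, masks)
      params <- do.call(rbind, lapply(seq_along(nuclei), function(i) {
        p <- nuclei[[i]]
        data.frame(id = i, row = p$row, col = p$col, a = p$a, b = p$b,
                   rot = p$rot, t(stats::setNames(p$amps, paste0("amp", 1:8))),
                   t(stats::setNames(p$phases, paste0("phase", 1:8))))
      }))
      return(structure(list(image = image, mask = mask * 1L, params = params,
                            seed = seed, spec = spec, nucleus_masks = masks),
                       class = "scene_sample"))
    }
  }
  stop(sprintf("could not reach foreground band (%.5f, %.5f) in %d attempts; spec may be near-infeasible",
               spec$fg_band[1], spec$fg_band[2], max_attempts))
}

render_image <- function(spec, mask, masks) {
  s <- spec$size
  coarse <- matrix(stats::rnorm(64, 0, spec$texture), 8, 8)
  tex <- tokens_to_map(
    bilinear_resize_fwd_cpp(matrix(as.vector(t(coarse)), ncol = 1L),
                            8L, 8L, s, s)[, 1L], s, s)
  image <- array(0, c(s, s, 3))
  for (ch in 1:3) image[, , ch] <- spec$bg[ch] + tex
  for (i in seq_along(masks)) {
    u <- stats::runif(1, 0.85, 1.15)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[masks[[i]]] <- spec$stain[ch] * u + tex[masks[[i]]]
      image[, , ch] <- plane
    }
  }
  image <- image + array(stats::rnorm(s * s * 3, 0, spec$noise), c(s, s, 3))
  pmin(pmax(image, 0), 1)
}

#' Re-render the mask of a scene from its parameter table
#'
#' @param params The `params` table of a `scene_sample`.
#' @param size Image side.
#' @return Integer 0/1 mask matrix.
#' @export
render_scene_mask <- function(params, size) {
  masks <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    render_nucleus(size, p$row, p$col, p$a, p$b, p$rot,
                   as.numeric(p[paste0("amp", 1:8)]),
                   as.numeric(p[paste0("phase", 1:8)]))
  })
  Reduce(`|`, masks) * 1L
}

dilate_mask <- function(m, radius = 1L) {
  H <- nrow(m)
  W <- ncol(m)
  out <- m
  for (i in seq_len(radius)) {
    d <- out
    d[-1, ] <- d[-1, ] | out[-H, ]
    d[-H, ] <- d[-H, ] | out[-1, ]
    e <- d
    e[, -1] <- e[, -1] | d[, -W]
    e[, -W] <- e[, -W] | d[, -1]
    out <- e
  }
  out
}

#' Foreground fraction, component count and adherent pairs of a scene
#'
#' Components use 8-connectivity. Adherent pairs are counted from the
#' per-nucleus masks (pairs whose masks touch or overlap); when only a bare
#' mask is supplied they are reported as `NA` unless fewer than two
#' components exist.
#'
#' @param x A `scene_sample` or a bare 0/1 mask matrix.
#' @return List with `fg_fraction`, `components`, `adherent_pairs`.
#' @export
scene_statistics <- function(x) {
  if (inherits(x, "scene_sample")) {
    mask <- x$mask
    masks <- x$nucleus_masks
    if (is.null(masks)) {
      masks <- lapply(seq_len(nrow(x$params)), function(i) {
        p <- x$params[i, ]
        render_nucleus(nrow(mask), p$row, p$col, p$a, p$b, p$rot,
                       as.numeric(p[paste0("amp", 1:8)]),
                       as.numeric(p[paste0("phase", 1:8)]))
      })
    }
  } else {
    mask <- x
    masks <- NULL
  }
  mask <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  lab <- label_components_cpp(mask)
  comps <- max(lab)
  pairs <- if (!is.null(masks)) {
    np <- 0L
    if (length(masks) >= 2) {
      for (i in seq_len(length(masks) - 1)) {
        di <- dilate_mask(masks[[i]])
        for (j in (i + 1):length(masks)) {
          if (any(di & masks[[j]])) np <- np + 1L
        }
      }
    }
    np
  } else if (comps < 2) 0L else NA_integer_
  list(fg_fraction = mean(mask), components = comps, adherent_pairs = pairs)
}

#' Generate a dataset of paired scene PNGs with a manifest
#'
#' Scenes use seeds `seed .. seed + n - 1` and are written as 8-bit PNG
#' image/mask pairs plus a `manifest.csv` listing paths, split tag and
#' per-scene statistics.
#'
#' @param spec A [scene_spec()].
#' @param n Number of scenes.
#' @param seed Base seed.
#' @param outdir Output directory (created if needed).
#' @param split Split tag recorded in the manifest.
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(spec, n, seed, outdir, split = "train") {
  stopifnot(n >= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seed + i - 1L)
    ip <- file.path(outdir, sprintf("image_%04d.png", i))
    mp <- file.path(outdir, sprintf("mask_%04d.png", i))
    write_image(sc$image, ip)
    write_mask(sc$mask, mp)
    st <- scene_statistics(sc)
    rows[[i]] <- data.frame(image = ip, mask = mp, split = split,
                            seed = seed + i - 1L,
                            fg_fraction = st$fg_fraction,
                            components = st$components,
                            adherent_pairs = st$adherent_pairs)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
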