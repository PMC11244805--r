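test_that("scene generation is deterministic in (spec, seed)", {
  spec <- scene_spec()
  a <- generate_scene(spec, 5)
  b <- generate_scene(spec, 5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$params, b$params)
  d <- generate_scene(spec, 6)
  expect_false(identical(a$image, d$image))
})

test_that("the parameter table regenerates the mask exactly", {
  spec <- scene_spec()
  s <- generate_scene(spec, 11)
  expect_identical(render_scene_mask(s$params, spec$size), s$mask)
})

test_that("adherent placement produces intersecting nuclei", {
  spec <- scene_spec(count = c(2L, 2L), overlap_prob = 1,
                     fg_band = c(0.01, 0.12))
  for (seed in 1:5) {
    s <- generate_scene(spec, seed)
    st <- scene_statistics(s)
    expect_gte(st$adherent_pairs, 1L)
  }
})

test_that("the extreme-scarcity spec hits its foreground band", {
  spec <- scene_spec_scarce(1024L)
  s <- generate_scene(spec, 3)
  frac <- mean(s$mask)
  expect_gte(frac, 5e-5)
  expect_lte(frac, 2e-4)
})

test_that("an infeasible foreground band is rejected with a message", {
  expect_error(scene_spec(size = 64, count = c(1L, 1L), radius = c(2, 2.5),
                          fg_band = c(0.5, 0.9)),
               "infeasible")
})

test_that("scene statistics count fraction, components and adherent pairs", {
  z <- matrix(0L, 32, 32)
  expect_equal(scene_statistics(z),
               list(fg_fraction = 0, components = 0L, adherent_pairs = 0L))
  one <- matrix(0L, 100, 100)
  one[45:49, 48:49] <- 1L  # a 10-pixel nucleus
  st <- scene_statistics(one)
  expect_equal(st$fg_fraction, 0.001)
  expect_equal(st$components, 1L)
  # two disjoint nuclei with a parameter table: 2 components, 0 pairs
  m1 <- matrix(FALSE, 32, 32); m1[5:8, 5:8] <- TRUE
  m2 <- matrix(FALSE, 32, 32); m2[20:23, 20:23] <- TRUE
  fake <- structure(list(mask = (m1 | m2) * 1L, nucleus_masks = list(m1, m2)),
                    class = "scene_sample")
  st2 <- scene_statistics(fake)
  expect_equal(st2$components, 2L)
  expect_equal(st2$adherent_pairs, 0L)
  # touching nuclei: 1 adherent pair
  m3 <- matrix(FALSE, 32, 32); m3[5:8, 9:12] <- TRUE
  fake2 <- structure(list(mask = (m1 | m3) * 1L, nucleus_masks = list(m1, m3)),
                     class = "scene_sample")
  expect_equal(scene_statistics(fake2)$adherent_pairs, 1L)
})

test_that("rougher boundaries have higher radial variance", {
  radial_var <- function(rough, seeds) {
    spec <- scene_spec(count = c(1L, 1L), roughness = rough,
                       fg_band = c(0.01, 0.08))
    mean(vapply(seeds, function(sd) {
      s <- generate_scene(spec, sd)
      m <- s$mask > 0
      # boundary pixels: foreground with a background 4-neighbour
      H <- nrow(m); W <- ncol(m)
      inner <- m
      inner[2:(H - 1), 2:(W - 1)] <- m[2:(H - 1), 2:(W - 1)] &
        m[1:(H - 2), 2:(W - 1)] & m[3:H, 2:(W - 1)] &
        m[2:(H - 1), 1:(W - 2)] & m[2:(H - 1), 3:W]
      bd <- which(m & !inner, arr.ind = TRUE)
      d <- sqrt((bd[, 1] - s$params$row[1])^2 + (bd[, 2] - s$params$col[1])^2)
      stats::var(d / mean(d))
    }, numeric(1)))
  }
  expect_gte(radial_var(0.35, 1:30), radial_var(0.02, 1:30))
})

test_that("nucleus interiors are darker than the background", {
  spec <- scene_spec()
  for (seed in 1:10) {
    s <- generate_scene(spec, 100 + seed)
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    expect_lt(mean(lum[s$mask == 1]), mean(lum[s$mask == 0]))
  }
})

test_that("dataset generation writes pairs, manifest and in-band statistics", {
  spec <- scene_spec()
  outdir <- withr::local_tempdir()
  mf <- generate_dataset(spec, 5, seed = 40, outdir)
  expect_equal(nrow(mf), 5L)
  expect_true(all(file.exists(mf$image)))
  expect_true(all(file.exists(mf$mask)))
  expect_true(all(mf$fg_fraction >= spec$fg_band[1] &
                    mf$fg_fraction <= spec$fg_band[2]))
  mf2 <- utils::read.csv(file.path(outdir, "manifest.csv"))
  expect_equal(nrow(mf2), 5L)
  # disjoint seed ranges give distinct scenes
  outdir2 <- withr::local_tempdir()
  mfB <- generate_dataset(spec, 2, seed = 4000, outdir2)
  p1 <- read_pair(mf$image[1], mf$mask[1])
  p2 <- read_pair(mfB$image[1], mfB$mask[1])
  expect_false(identical(p1$image, p2$image))
})
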