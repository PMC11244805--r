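## Paired geometric augmentation: flips, right-angle rotations and random
## cropping, applied identically to image and mask (mask is label-valued so
## only exact pixel re-indexing is used — the nearest-neighbour contract).

rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot90_img <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    img <- if (length(dim(img)) == 3L) {
      aperm(array(apply(img, 3, rot90_mat),
                  c(dim(img)[2], dim(img)[1], dim(img)[3])), c(1, 2, 3))
    } else {
      rot90_mat(img)
    }
  }
  img
}

#' Random paired augmentation of an image/mask pair
#'
#' Applies (with probability 1/2 each) horizontal and vertical flips, a
#' random rotation from {0, 90, 180, 270} degrees, and a random crop to
#' `crop_size`; image and mask receive the identical transform. With a
#' `seed` the result is deterministic and the caller's RNG state is
#' untouched.
#'
#' @param image Array c(H, W, 3).
#' @param mask Integer matrix c(H, W).
#' @param crop_size Output side length (must not exceed the input after
#'   rotation); `NULL` keeps the full extent.
#' @param seed Optional integer seed.
#' @return List with transformed `image` and `mask`.
#' @export
random_augment <- function(image, mask, crop_size = NULL, seed = NULL) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (stats::runif(1) < 0.5) {  # horizontal flip
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {  # vertical flip
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  k <- sample(0:3, 1L)
  image <- rot90_img(image, k)
  mask <- rot90_img(mask, k)
  if (!is.null(crop_size)) {
    H <- dim(image)[1]
    W <- dim(image)[2]
    if (crop_size > H || crop_size > W) {
      stop(sprintf("crop size %d exceeds input extent %dx%d", crop_size, H, W))
    }
    r0 <- sample.int(H - crop_size + 1L, 1L)
    c0 <- sample.int(W - crop_size + 1L, 1L)
    image <- image[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L), ,
                   drop = FALSE]
    mask <- mask[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L),
                 drop = FALSE]
  }
  list(image = image, mask = mask)
}
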