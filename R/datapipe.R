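# Patch pipeline: grid decomposition with boundary re-crops and zero
# padding, foreground-filtered random patches, train/validation splitting,
# and photometric/geometric augmentation.

#' Patch grid configuration
#'
#' `patch_size` is the square patch side; the structured grid has spacing
#' `grid_dx` = `grid_dy` = `patch_size` (the standard tiling).  Random
#' patches are kept only when their foreground/background pixel-count ratio
#' strictly exceeds `fg_ratio_threshold`.  `split_ratio` is the training
#' fraction of the patch-level train/validation split.
#'
#' @param patch_size patch side in pixels.
#' @param grid_dx,grid_dy grid spacing in pixels (default `patch_size`).
#' @param fg_ratio_threshold foreground/background ratio threshold (strict).
#' @param n_random_patches_per_image random patches drawn per image.
#' @param split_ratio training fraction in `(0, 1)`.
#' @param seed integer seed for random patches and the split.
#' @return an object of class `patch_grid_config`.
#' @export
patch_grid_config <- function(patch_size = 256L, grid_dx = patch_size,
                              grid_dy = patch_size,
                              fg_ratio_threshold = 0.4,
                              n_random_patches_per_image = 4L,
                              split_ratio = 0.8, seed = 0L) {
  stopifnot(patch_size >= 1, grid_dx >= 1, grid_dy >= 1,
            split_ratio > 0, split_ratio < 1,
            n_random_patches_per_image >= 0, fg_ratio_threshold >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 grid_dx = as.integer(grid_dx), grid_dy = as.integer(grid_dy),
                 fg_ratio_threshold = fg_ratio_threshold,
                 n_random_patches_per_image =
                   as.integer(n_random_patches_per_image),
                 split_ratio = split_ratio, seed = as.integer(seed)),
            class = "patch_grid_config")
}

.patch_record <- function(source_id, row0, col0, image_patch, mask_patch,
                          was_padded, origin) {
  structure(list(source_id = source_id, row0 = as.integer(row0),
                 col0 = as.integer(col0), image_patch = image_patch,
                 mask_patch = mask_patch, was_padded = was_padded,
                 origin = origin),
            class = "patch_record")
}

.extract_patch <- function(image, row0, col0, ps) {
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, ps, ps)
  rr <- seq.int(row0 + 1L, min(row0 + ps, H))
  cc <- seq.int(col0 + 1L, min(col0 + ps, W))
  out[seq_along(rr), seq_along(cc)] <- image[rr, cc]
  out
}

.axis_offsets <- function(n, ps, delta) {
  if (n <= ps) return(list(off = 0L, pad = n < ps))
  off <- seq.int(0L, n - ps, by = delta)
  last <- n - ps
  if (!(last %in% off)) off <- c(off, last)
  list(off = as.integer(off), pad = FALSE)
}

#' Grid decomposition of an image into patches
#'
#' Emits every patch whose top-left corner lies on the structured grid and
#' which fits inside the image; dimensions smaller than the patch size are
#' zero-padded (`was_padded = TRUE`); dimensions larger than but indivisible
#' by the patch size get boundary re-crops whose far edge coincides with the
#' image edge.  The union of emitted patch footprints covers every pixel.
#'
#' @param image numeric image matrix.
#' @param mask optional instance or binary mask of the same size; patch
#'   masks are binarised (`> 0`).
#' @param config a [patch_grid_config()].
#' @param source_id identifier recorded on each patch.
#' @return list of `patch_record` objects with fields `source_id`, `row0`,
#'   `col0` (0-based offsets), `image_patch`, `mask_patch`, `was_padded`,
#'   `origin` (`"grid"` or `"boundary"`).
#' @export
grid_patches <- function(image, mask = NULL, config = patch_grid_config(),
                         source_id = "image") {
  if (is.null(dim(image)) || any(dim(image) == 0L))
    stop("empty image")
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop("image and mask dimensions differ")
  ps <- config$patch_size
  ro <- .axis_offsets(nrow(image), ps, config$grid_dy)
  co <- .axis_offsets(ncol(image), ps, config$grid_dx)
  bin_mask <- if (!is.null(mask)) (mask > 0) * 1L else NULL
  out <- list()
  for (r0 in ro$off) for (c0 in co$off) {
    origin <- if (r0 %% config$grid_dy == 0L && c0 %% config$grid_dx == 0L)
      "grid" else "boundary"
    out[[length(out) + 1L]] <- .patch_record(
      source_id, r0, c0,
      .extract_patch(image, r0, c0, ps),
      if (!is.null(bin_mask)) .extract_patch(bin_mask, r0, c0, ps),
      ro$pad || co$pad, origin)
  }
  out
}

#' Random foreground-filtered patches
#'
#' Draws uniformly positioned patches and keeps those whose foreground to
#' background pixel-count ratio strictly exceeds the configured threshold.
#' Rejection sampling is bounded, so fewer than the requested number of
#' patches may be returned; images smaller than the patch size yield none.
#'
#' @inheritParams grid_patches
#' @return list of `patch_record` objects with `origin = "random"`.
#' @export
random_patches <- function(image, mask, config = patch_grid_config(),
                           source_id = "image") {
  stopifnot(all(dim(mask) == dim(image)))
  ps <- config$patch_size
  H <- nrow(image); W <- ncol(image)
  if (H < ps || W < ps) return(list())
  bin_mask <- (mask > 0) * 1L
  n_target <- config$n_random_patches_per_image
  out <- list()
  .with_stream(config$seed, 1L, {
    attempts <- 0L
    max_attempts <- max(20L * n_target, 1L)
    while (length(out) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      r0 <- sample.int(H - ps + 1L, 1L) - 1L
      c0 <- sample.int(W - ps + 1L, 1L) - 1L
      mp <- .extract_patch(bin_mask, r0, c0, ps)
      fg <- sum(mp)
      bg <- ps * ps - fg
      ratio <- if (bg == 0L) Inf else fg / bg
      if (ratio > config$fg_ratio_threshold)
        out[[length(out) + 1L]] <- .patch_record(
          source_id, r0, c0, .extract_patch(image, r0, c0, ps), mp,
          FALSE, "random")
    }
  })
  out
}

#' Split patches into training and validation sets
#'
#' Random patch-level split with `round(split_ratio * n)` training patches;
#' the two subsets partition the input and the split is deterministic under
#' the configured seed.
#'
#' @param patches non-empty list of patches.
#' @param config a [patch_grid_config()].
#' @return list with elements `train` and `val`.
#' @export
split_train_val <- function(patches, config = patch_grid_config()) {
  n <- length(patches)
  if (n == 0L) stop("cannot split an empty patch list")
  n_train <- round(config$split_ratio * n)
  idx <- .with_stream(config$seed, 2L, sample.int(n, n_train))
  list(train = patches[sort(idx)], val = patches[setdiff(seq_len(n), idx)])
}

#' Augmentation configuration
#'
#' Probabilities and magnitudes of the augmentation transforms: geometric
#' flips/rotations (applied identically to image and mask) and photometric
#' blurring (Gaussian, median or average), contrast, hue and colour
#' saturation adjustments (image only).  Hue/saturation act on a grey-scale
#' image by stacking it to three identical channels, perturbing in HSV space
#' and converting back through luminance.  With all probabilities zero the
#' transform is the identity.
#'
#' @param p_flip_h,p_flip_v,p_rot90 probabilities of the geometric ops.
#' @param p_blur probability of one blur (type drawn uniformly).
#' @param blur_sigma range of the Gaussian blur standard deviation.
#' @param p_contrast probability of a contrast change.
#' @param contrast_range multiplicative contrast factor range.
#' @param p_hue,hue_shift probability and maximal shift of the hue rotation.
#' @param p_saturation,sat_range probability and factor range of the
#'   saturation change.
#' @return an object of class `aug_config`.
#' @export
aug_config <- function(p_flip_h = 0.5, p_flip_v = 0.5, p_rot90 = 0.5,
                       p_blur = 0.3, blur_sigma = c(0.5, 1.5),
                       p_contrast = 0.3, contrast_range = c(0.7, 1.3),
                       p_hue = 0.2, hue_shift = 0.05,
                       p_saturation = 0.2, sat_range = c(0.7, 1.3)) {
  structure(as.list(environment()), class = "aug_config")
}

.rot90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  m
}

.hue_sat_adjust <- function(img, dh, ds) {
  v <- pmin(pmax(as.vector(img), 0), 1)
  hsv_m <- rgb2hsv(rbind(v, v, v) * 255, maxColorValue = 255)
  h <- (hsv_m[1L, ] + dh) %% 1
  s <- pmin(pmax(hsv_m[2L, ] * ds, 0), 1)
  rgb_m <- col2rgb(hsv(h, s, hsv_m[3L, ])) / 255
  lum <- 0.299 * rgb_m[1L, ] + 0.587 * rgb_m[2L, ] + 0.114 * rgb_m[3L, ]
  matrix(lum, nrow(img), ncol(img))
}

#' Augment an image/mask pair
#'
#' Core augmentation routine on a full image (or patch) and its binary mask.
#' Geometric transforms are applied identically to both; photometric
#' transforms touch the image only.  Output values are clipped to `[0, 1]`.
#' Deterministic for a fixed seed.
#'
#' @param image numeric image matrix in `[0, 1]`.
#' @param mask binary mask matrix (or `NULL`).
#' @param seed integer seed.
#' @param config an [aug_config()].
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, seed, config = aug_config()) {
  .with_stream(seed, 3L, {
    img <- image; msk <- mask
    if (config$p_flip_h > 0 && runif(1) < config$p_flip_h) {
      img <- img[, ncol(img):1L, drop = FALSE]
      if (!is.null(msk)) msk <- msk[, ncol(msk):1L, drop = FALSE]
    }
    if (config$p_flip_v > 0 && runif(1) < config$p_flip_v) {
      img <- img[nrow(img):1L, , drop = FALSE]
      if (!is.null(msk)) msk <- msk[nrow(msk):1L, , drop = FALSE]
    }
    if (config$p_rot90 > 0 && runif(1) < config$p_rot90 &&
        nrow(img) == ncol(img)) {
      k <- sample.int(3L, 1L)
      img <- .rot90(img, k)
      if (!is.null(msk)) msk <- .rot90(msk, k)
    }
    if (config$p_blur > 0 && runif(1) < config$p_blur) {
      type <- sample(c("gaussian", "median", "average"), 1L)
      img <- switch(type,
        gaussian = EBImage::gblur(img,
                                  sigma = runif(1, config$blur_sigma[1L],
                                                config$blur_sigma[2L])),
        median = as.matrix(EBImage::medianFilter(pmin(pmax(img, 0), 1), 1L)),
        average = as.matrix(EBImage::filter2(img, matrix(1 / 9, 3L, 3L))))
      img <- matrix(as.numeric(img), nrow(image), ncol(image))
    }
    if (config$p_contrast > 0 && runif(1) < config$p_contrast) {
      f <- runif(1, config$contrast_range[1L], config$contrast_range[2L])
      img <- (img - mean(img)) * f + mean(img)
    }
    if (config$p_hue > 0 && runif(1) < config$p_hue)
      img <- .hue_sat_adjust(img, runif(1, -config$hue_shift,
                                        config$hue_shift), 1)
    if (config$p_saturation > 0 && runif(1) < config$p_saturation)
      img <- .hue_sat_adjust(img, 0, runif(1, config$sat_range[1L],
                                           config$sat_range[2L]))
    list(image = pmin(pmax(img, 0), 1), mask = msk)
  })
}

#' Augment a patch record
#'
#' Convenience wrapper of [augment_pair()] operating on a `patch_record`.
#'
#' @param patch a `patch_record`.
#' @param seed integer seed.
#' @param config an [aug_config()].
#' @return the augmented `patch_record`.
#' @export
augment <- function(patch, seed, config = aug_config()) {
  stopifnot(inherits(patch, "patch_record"))
  a <- augment_pair(patch$image_patch, patch$mask_patch, seed, config)
  patch$image_patch <- a$image
  patch$mask_patch <- a$mask
  patch
}
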