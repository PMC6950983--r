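test_that("grid decomposition matches the published tiling rules", {
  cfg <- patch_grid_config()
  offs <- function(ps) t(vapply(ps, function(p) c(p$row0, p$col0),
                                integer(2)))

  g1 <- grid_patches(matrix(0, 256, 256), config = cfg)
  expect_length(g1, 1L)
  expect_identical(c(g1[[1]]$row0, g1[[1]]$col0), c(0L, 0L))
  expect_false(g1[[1]]$was_padded)

  g4 <- grid_patches(matrix(0, 512, 512), config = cfg)
  expect_length(g4, 4L)
  expect_setequal(apply(offs(g4), 1, paste, collapse = ","),
                  c("0,0", "0,256", "256,0", "256,256"))
  expect_true(all(vapply(g4, `[[`, "", "origin") == "grid"))

  g300 <- grid_patches(matrix(0, 300, 300), config = cfg)
  expect_length(g300, 4L)
  expect_setequal(apply(offs(g300), 1, paste, collapse = ","),
                  c("0,0", "0,44", "44,0", "44,44"))
  # the three re-crops end exactly at the image boundary
  expect_identical(sum(vapply(g300, `[[`, "", "origin") == "boundary"), 3L)

  gp <- grid_patches(matrix(1, 100, 100), config = cfg)
  expect_length(gp, 1L)
  expect_true(gp[[1]]$was_padded)
  expect_identical(dim(gp[[1]]$image_patch), c(256L, 256L))
  expect_true(all(gp[[1]]$image_patch[101:256, ] == 0))

  expect_error(grid_patches(matrix(0, 0, 5), config = cfg), "empty")
})

test_that("grid patches cover every pixel for randomized sizes", {
  cfg <- patch_grid_config()
  set.seed(42)
  for (i in 1:100) {
    H <- sample(256:1024, 1); W <- sample(256:1024, 1)
    ps <- grid_patches(matrix(0, H, W), config = cfg)
    expect_identical(length(ps), as.integer(ceiling(H / 256) * ceiling(W / 256)))
    cover <- matrix(0L, H, W)
    for (p in ps) {
      rr <- (p$row0 + 1):min(p$row0 + 256, H)
      cc <- (p$col0 + 1):min(p$col0 + 256, W)
      cover[rr, cc] <- cover[rr, cc] + 1L
    }
    expect_true(all(cover >= 1L))
    # grid-origin patches are pairwise disjoint: multiply-covered pixels
    # only arise from boundary re-crops
    if (H %% 256 == 0 && W %% 256 == 0) expect_true(all(cover == 1L))
  }
})

test_that("random patches enforce the strict foreground/background ratio", {
  cfg <- patch_grid_config(patch_size = 14L, n_random_patches_per_image = 5L,
                           seed = 9L)
  img <- matrix(0.5, 14, 14)

  expect_length(random_patches(img, matrix(0L, 14, 14), cfg), 0L)
  all_fg <- random_patches(img, matrix(1L, 14, 14), cfg)
  expect_length(all_fg, 5L)
  expect_true(all(vapply(all_fg, `[[`, "", "origin") == "random"))

  # fg/bg exactly 0.4 (56 / 140 pixels): strictly rejected
  m <- matrix(0L, 14, 14); m[seq_len(56)] <- 1L
  expect_length(random_patches(img, m, cfg), 0L)
  cfg_low <- patch_grid_config(patch_size = 14L,
                               n_random_patches_per_image = 5L,
                               fg_ratio_threshold = 0.39, seed = 9L)
  expect_length(random_patches(img, m, cfg_low), 5L)

  # too-small images yield no random patches
  expect_length(random_patches(matrix(0, 8, 8), matrix(1L, 8, 8), cfg), 0L)
})

test_that("train/validation split is a deterministic 8:2 partition", {
  cfg <- patch_grid_config(seed = 3L)
  mk <- function(n) lapply(seq_len(n), function(i)
    nucleiseg:::.patch_record("s", 0L, 0L, matrix(i, 2, 2),
                              matrix(0L, 2, 2), FALSE, "grid"))
  sp <- split_train_val(mk(10L), cfg)
  expect_length(sp$train, 8L)
  expect_length(sp$val, 2L)
  sp2 <- split_train_val(mk(10L), cfg)
  expect_identical(sp, sp2)
  expect_error(split_train_val(list(), cfg), "empty")

  set.seed(77)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    sp <- split_train_val(mk(n), patch_grid_config(seed = i))
    expect_identical(length(sp$train), as.integer(round(0.8 * n)))
    ids <- c(vapply(sp$train, function(p) p$image_patch[1], 1),
             vapply(sp$val, function(p) p$image_patch[1], 1))
    expect_setequal(ids, seq_len(n))  # partition: union, no duplicates
  }
})

test_that("augmentation is identity at zero probability and mask-consistent", {
  s <- generate_sample(tiny_synth(), 1L)
  p <- grid_patches(s$image, s$mask,
                    patch_grid_config(patch_size = 64L))[[1]]
  off <- aug_config(p_flip_h = 0, p_flip_v = 0, p_rot90 = 0, p_blur = 0,
                    p_contrast = 0, p_hue = 0, p_saturation = 0)
  expect_identical(augment(p, seed = 5L, config = off), p)

  # geometric-only: the mask receives exactly the image's transform
  geo <- aug_config(p_flip_h = 1, p_flip_v = 1, p_rot90 = 1, p_blur = 0,
                    p_contrast = 0, p_hue = 0, p_saturation = 0)
  grid_img <- matrix(seq_len(64 * 64) / (64 * 64), 64)
  a <- augment_pair(grid_img, grid_img, seed = 8L, config = geo)
  expect_identical(a$image, a$mask)
  expect_false(identical(a$image, grid_img))

  # determinism and clipping
  heavy <- aug_config(p_contrast = 1, contrast_range = c(3, 3))
  b1 <- augment(p, seed = 21L, config = heavy)
  b2 <- augment(p, seed = 21L, config = heavy)
  expect_identical(b1, b2)
  expect_true(all(b1$image_patch >= 0 & b1$image_patch <= 1))
  expect_identical(b1$mask_patch, p$mask_patch)  # photometric spares the mask
})
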