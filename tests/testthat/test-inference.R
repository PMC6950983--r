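test_that("single-patch prediction equals a direct forward pass", {
  m <- tiny_model(seed = 6L)
  img <- matrix(runif(64 * 64), 64)
  grid <- patch_grid_config(patch_size = 64L)
  expect_identical(predict_image(m, img, preproc = NULL, grid = grid),
                   model_forward(m, img))
})

test_that("overlap fusion takes the pixel-wise maximum over covering patches", {
  m <- tiny_model(seed = 6L)
  grid <- patch_grid_config(patch_size = 64L)
  img <- matrix(runif(96 * 96), 96)
  prob <- predict_image(m, img, preproc = NULL, grid = grid)
  expect_identical(dim(prob), c(96L, 96L))
  # recompute the four covering patches by hand (offsets 0 and 32)
  offs <- c(0L, 32L)
  acc <- matrix(-Inf, 96, 96)
  for (r0 in offs) for (c0 in offs) {
    p <- model_forward(m, img[r0 + 1:64, c0 + 1:64])
    acc[r0 + 1:64, c0 + 1:64] <- pmax(acc[r0 + 1:64, c0 + 1:64], p)
  }
  expect_equal(prob, acc, tolerance = 1e-12)
})

test_that("padding at inference is cropped back to the input shape", {
  m <- tiny_model(seed = 6L)
  grid <- patch_grid_config(patch_size = 64L)
  img <- matrix(runif(40 * 50), 40)
  prob <- predict_image(m, img, preproc = NULL, grid = grid)
  expect_identical(dim(prob), c(40L, 50L))
  # the visible region equals the padded patch's corresponding window
  padded <- matrix(0, 64, 64); padded[1:40, 1:50] <- img
  expect_equal(prob, model_forward(m, padded)[1:40, 1:50],
               tolerance = 1e-12)
})

test_that("binarisation and cleanup follow the area rules and are idempotent", {
  cfg <- postproc_config(prob_threshold = 0.5, min_object_area = 300L,
                         max_hole_area = 300L)
  # uniform probability above threshold: one giant component survives
  all6 <- matrix(0.6, 30, 30)
  expect_true(all(binarize_and_clean(all6, cfg) == 1L))
  # strictly-greater threshold: exactly 0.5 is background
  expect_true(all(binarize_and_clean(matrix(0.5, 8, 8), cfg) == 0L))

  # a 10-pixel object is removed under min_object_area = 300
  small <- matrix(0, 40, 40); small[10:11, 10:14] <- 0.9
  expect_true(all(binarize_and_clean(small, cfg) == 0L))

  # a donut with a 49-pixel hole is filled solid
  donut <- matrix(0, 40, 40)
  donut[8:32, 8:32] <- 0.9
  donut[15:21, 15:21] <- 0.1
  cleaned <- binarize_and_clean(donut, cfg)
  expect_true(all(cleaned[15:21, 15:21] == 1L))
  expect_identical(sum(cleaned), 25L * 25L)

  # holes touching the border are background, not holes
  open_c <- matrix(0, 20, 20); open_c[5:15, 5:15] <- 0.9
  open_c[1:10, 9:11] <- 0  # channel to the border
  cfg_small <- postproc_config(min_object_area = 10L, max_hole_area = 300L)
  cleaned2 <- binarize_and_clean(open_c, cfg_small)
  expect_true(all(cleaned2[1:4, 9:11] == 0L))

  # idempotence on an arbitrary probability map
  set.seed(1)
  pr <- matrix(runif(60 * 60), 60)
  once <- binarize_and_clean(pr, cfg_small)
  expect_identical(binarize_and_clean(once * 0.9 + 0.05, cfg_small), once)
})

test_that("instance labelling follows the connectivity convention", {
  expect_identical(max(label_instances(matrix(0L, 5, 5))), 0L)
  two <- matrix(0L, 8, 8); two[1:2, 1:2] <- 1L; two[6:7, 6:7] <- 1L
  lab <- label_instances(two)
  expect_setequal(unique(as.vector(lab[lab > 0])), c(1L, 2L))
  # diagonal touch: one component at 8-connectivity, two at 4
  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_identical(max(label_instances(diagm, connectivity = 8L)), 1L)
  expect_identical(max(label_instances(diagm, connectivity = 4L)), 2L)
  expect_error(label_instances(matrix(c(0, 3), 1)), "binary")
})
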