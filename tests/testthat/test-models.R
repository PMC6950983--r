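test_that("configuration invariants are enforced", {
  expect_error(model_config("unet_plus", base_filters = 7L), "multiple of 2")
  expect_error(model_config("unet", depth = 1L), "depth")
  expect_error(model_config("unet_plus", depth = 4L), "depth = 5")
  expect_error(model_config("unet", input_size = 100L), "divisible")
  expect_error(model_config("bogus"))
  # architecture-dependent defaults
  expect_true(model_config("unet_plus")$batch_norm)
  expect_false(model_config("unet")$batch_norm)
  expect_equal(model_config("unet_pp", 16L)$l2_lambda, 1e-4)
  expect_equal(model_config("unet_pp", 8L)$l2_lambda, 0)
})

test_that("channel width scales quadratically in the base filter count", {
  for (arch in c("unet", "unet_pp", "unet_plus")) {
    c16 <- count_weights(build_model(model_config(arch, 16L), seed = 1L))
    c8 <- count_weights(build_model(model_config(arch, 8L), seed = 1L))
    expect_lt(abs(c16 / c8 - 4), 0.12)  # within 3%
  }
})

test_that("transposed-conv mode carries more weights than repeat-upsampling", {
  tc <- count_weights(build_model(
    model_config("unet_plus", 8L, upsample_mode = "transposed_conv"),
    seed = 1L))
  us <- count_weights(build_model(
    model_config("unet_plus", 8L, upsample_mode = "upsample"), seed = 1L))
  # TC adds one 3x3 kernel per decoder level and halves the first conv's
  # input: the difference is exactly 765 B^2 + 15 B
  expect_identical(tc - us, 765L * 64L + 15L * 8L)
})

test_that("architecture summary is a complete accounting of the weights", {
  for (arch in c("unet", "unet_pp", "unet_plus")) {
    cfg <- model_config(arch, 8L, input_size = 256L)
    tab <- summarize_architecture(cfg)
    expect_identical(sum(tab$n_params),
                     count_weights(build_model(cfg, seed = 0L)))
    head_row <- tab[tab$block == "head", ]
    expect_match(head_row$op, "1x1")
    expect_match(head_row$output_shape, "x1$")
  }
  # level-3 conv blocks carry 4B filters
  tab <- summarize_architecture(model_config("unet_plus", 8L))
  expect_match(tab[tab$block == "c3_1", "output_shape"], "x32$")
  expect_match(tab[tab$block == "c3_2", "output_shape"], "x32$")
})

test_that("forward passes produce sigmoid probabilities at input shape", {
  x <- matrix(0, 64, 64)
  for (arch in c("unet", "unet_pp", "unet_plus")) {
    for (mode in c("transposed_conv", "upsample")) {
      m <- tiny_model(arch, mode = mode)
      p <- model_forward(m, x)
      expect_identical(dim(p), c(64L, 64L))
      expect_true(all(is.finite(p)))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  m <- tiny_model()
  x <- matrix(runif(64 * 64), 64)
  p1 <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(model_forward(m2, x), p1)
  unlink(path)
})

test_that("model initialisation is reproducible under a seed", {
  m1 <- tiny_model(seed = 9L)
  m2 <- tiny_model(seed = 9L)
  x <- matrix(runif(64 * 64), 64)
  expect_identical(model_forward(m1, x), model_forward(m2, x))
})
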