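test_that("the Dice coefficient matches set-overlap arithmetic", {
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1
  expect_equal(dice_coefficient(a, a), 1, tolerance = 1e-6)

  b <- matrix(0, 4, 4); b[3, 1:4] <- 1    # disjoint from a
  s <- 1e-6
  expect_equal(dice_coefficient(a, b, s), s / (8 + s))

  # |A| = |B| = 4 with overlap 2 -> 2*2 / (4+4) = 0.5
  p <- matrix(0, 4, 4); p[1, 3:4] <- 1; p[2, 1:2] <- 1
  expect_equal(dice_coefficient(a, p, s), (2 * 2 + s) / (8 + s))

  expect_error(dice_coefficient(a, matrix(0, 2, 2)), "shape")
})

test_that("the objective matches hand-computed scalar arithmetic", {
  cfg <- train_config(dice_smooth = 1e-6)
  yt <- matrix(c(1, 1, 0, 0), 1)
  yp <- matrix(c(0.8, 0.8, 0.2, 0.2), 1)
  bce <- -mean(c(log(0.8), log(0.8), log(0.8), log(0.8)))
  d <- (2 * 1.6 + 1e-6) / (2 + 2 + 1e-6)
  expect_equal(loss(yt, yp, cfg), bce - log(d), tolerance = 1e-6)

  # lambda_bce = 0 isolates the negative-log-Dice term
  cfg0 <- train_config(lambda_bce = 0)
  expect_equal(loss(yt, yp, cfg0), -log(d), tolerance = 1e-6)

  # perfect confident prediction drives the loss to ~0
  ypp <- matrix(c(1 - 1e-7, 1 - 1e-7, 1e-7, 1e-7), 1)
  expect_lt(loss(yt, ypp, cfg), 1e-5)

  expect_error(loss(yt, matrix(c(0.5, 0.5, 0.5, 1.2), 1), cfg), "\\[0, 1\\]")
  expect_error(loss(yt, matrix(0.5, 2, 1), cfg), "shape")
})

make_tiny_patches <- function(n = 4L) {
  cfg <- tiny_synth()
  lapply(seq_len(n), function(i) {
    s <- generate_sample(cfg, i)
    list(image = s$image, mask = (s$mask > 0) * 1)
  })
}

test_that("training records history and returns the best checkpoint", {
  patches <- make_tiny_patches(4L)
  m <- tiny_model(seed = 2L)
  cfg <- train_config(lr = 2e-3, epochs = 4L, batch_size = 2L, seed = 1L)
  res <- train(m, patches[1:3], patches[4], cfg)
  expect_identical(nrow(res$history), 4L)
  expect_identical(res$history$epoch, 1:4)
  expect_true(all(is.finite(res$history$train_loss)))
  # checkpoint rule: the returned model's monitored loss equals the best
  expect_equal(res$best_val_loss,
               min(c(nucleiseg:::.eval_loss(res$model, patches[4], cfg),
                     res$history$val_loss)),
               tolerance = 1e-6)
  # learning happened
  expect_lt(min(res$history$val_loss), res$history$val_loss[1] + 1)
  expect_error(train(m, list(), patches, cfg), "empty")
})

test_that("fine-tuning respects the reduced-rate protocol", {
  patches <- make_tiny_patches(3L)
  m <- tiny_model(seed = 4L)
  cfg <- train_config(lr = 2e-3, epochs = 2L, finetune_epochs = 2L,
                      finetune_lr = 1e-4, batch_size = 2L, seed = 1L)
  expect_lt(cfg$finetune_lr, cfg$lr)
  res <- train(m, patches, list(), cfg)

  # zero-epoch fine-tuning leaves the model unchanged
  cfg0 <- train_config(lr = 2e-3, finetune_epochs = 0L, batch_size = 2L)
  ft0 <- finetune(res$model, patches, list(), cfg0)
  x <- patches[[1]]$image
  expect_identical(model_forward(ft0$model, x), model_forward(res$model, x))

  # fine-tuning never worsens the best monitored loss
  ft <- finetune(res$model, patches, list(), cfg)
  expect_lte(ft$best_val_loss, res$best_val_loss + 1e-9)

  bad <- train_config(lr = 1e-4, finetune_lr = 5e-3)
  expect_error(finetune(res$model, patches, list(), bad), "finetune_lr")
})

test_that("training is reproducible under a fixed seed", {
  patches <- make_tiny_patches(2L)
  cfg <- train_config(lr = 1e-3, epochs = 2L, batch_size = 2L, seed = 5L)
  r1 <- train(tiny_model(seed = 3L), patches, list(), cfg)
  r2 <- train(tiny_model(seed = 3L), patches, list(), cfg)
  expect_identical(r1$history, r2$history)
})
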