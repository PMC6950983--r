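test_that("the IOU matrix counts pixel overlap cell by cell", {
  one <- rect_mask(8, 8, 2:4, 2:4)
  expect_identical(iou_matrix(one, one), matrix(1, 1, 1))

  two_gt <- rect_mask(8, 8, 1:2, 1:2) + rect_mask(8, 8, 6:7, 6:7, 2L)
  far <- rect_mask(8, 8, 4:5, 4:5)
  expect_true(all(iou_matrix(two_gt, far) == 0))

  # 4-px square vs the same square shifted to overlap 2 px: 2/6
  g <- rect_mask(8, 8, 2:3, 2:3)
  p <- rect_mask(8, 8, 2:3, 3:4)
  expect_equal(iou_matrix(g, p)[1, 1], 2 / 6)

  expect_error(iou_matrix(g, rect_mask(4, 4, 1:2, 1:2)), "shape")
})

test_that("matching yields the published TP/FN/FP semantics", {
  three <- rect_mask(16, 16, 1:3, 1:3) + rect_mask(16, 16, 6:8, 6:8, 2L) +
    rect_mask(16, 16, 12:14, 12:14, 3L)
  m <- match_cells(three, three)
  expect_identical(m$per_gt_iou, rep(1, 3))
  expect_true(all(m$counts$tp == 3L & m$counts$fn == 0L & m$counts$fp == 0L))
  expect_equal(precision(m), 1)

  empty_pred <- matrix(0L, 16, 16)
  m2 <- match_cells(three[1:16, 1:16], empty_pred)
  expect_identical(m2$per_gt_iou, rep(0, 3))
  expect_true(all(m2$counts$tp == 0L & m2$counts$fn == 3L &
                    m2$counts$fp == 0L))
  expect_equal(precision(m2), 0)

  # single pair with IOU 0.6: TP only at thresholds 0.50, 0.55 (strict >)
  pair <- iou_pair(0.6)
  expect_equal(iou_matrix(pair$gt, pair$pred)[1, 1], 0.6)
  m3 <- match_cells(pair$gt, pair$pred)
  expect_identical(m3$counts$tp, c(1L, 1L, rep(0L, 8)))
  expect_identical(m3$counts$fn + m3$counts$tp, rep(1L, 10))
  expect_equal(precision(m3), 0.2)
  expect_equal(m3$per_gt_iou, 0.6)
  # TP_k is non-increasing in the threshold
  expect_true(all(diff(m3$counts$tp) <= 0))
})

test_that("the greedy matcher equals the exhaustive assignment oracle", {
  cfg <- eval_config()
  for (seed in 1:50) {
    pair <- random_mask_pair(seed)
    M <- iou_matrix(pair$gt, pair$pred)
    m <- match_cells(pair$gt, pair$pred, cfg)
    for (k in seq_along(cfg$thresholds)) {
      expect_identical(m$counts$tp[k],
                       oracle_max_matching(M, cfg$thresholds[k]),
                       info = sprintf("seed %d, T=%.2f", seed,
                                      cfg$thresholds[k]))
    }
    expect_true(all(diff(m$counts$tp) <= 0))
    expect_identical(m$counts$tp + m$counts$fn,
                     rep(nrow(M), length(cfg$thresholds)))
  }
})

test_that("dataset aggregation reports mean, population sd and precision", {
  perfect <- rect_mask(16, 16, 2:6, 2:6)
  rep1 <- evaluate_dataset(list(list(gt = perfect, pred = perfect),
                                list(gt = perfect, pred = perfect)))
  expect_equal(rep1$mean_iou, 1)
  expect_equal(rep1$sd_iou, 0)
  expect_equal(rep1$mean_precision, 1)

  # per-image average IOUs of exactly 0.6 and 0.8 -> 0.7 +/- 0.1
  rep2 <- evaluate_dataset(list(iou_pair(0.6), iou_pair(0.8)))
  expect_equal(rep2$mean_iou, 0.7)
  expect_equal(rep2$sd_iou, 0.1)

  # zero-gt / zero-pred image counts as vacuously perfect
  blank <- matrix(0L, 8, 8)
  rep3 <- evaluate_dataset(list(list(gt = blank, pred = blank)))
  expect_equal(rep3$per_image$avg_iou, 1)
  expect_equal(rep3$mean_precision, 1)

  expect_error(evaluate_dataset(list()), "empty")
})

test_that("self-evaluation of any instance mask is perfect", {
  for (seed in c(2, 9)) {
    s <- generate_sample(tiny_synth(), seed)
    m <- match_cells(s$mask, s$mask)
    expect_true(all(m$per_gt_iou == 1))
    expect_equal(precision(m), 1)
  }
})
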