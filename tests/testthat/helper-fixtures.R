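# Shared fixtures: tiny configurations, toy instance masks, and the
# exhaustive matching oracle used to validate the greedy cell matcher.

tiny_synth <- function(...) {
  args <- list(image_height = 64L, image_width = 64L,
               n_nuclei_range = c(3L, 6L), radius_range = c(4, 7),
               noise_sigma = 0.02, seed = 123L)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

tiny_model <- function(arch = "unet_plus", B = 2L,
                       mode = "transposed_conv", seed = 1L) {
  build_model(model_config(arch, base_filters = B, upsample_mode = mode,
                           input_size = 64L), seed = seed)
}

# Axis-aligned rectangle helper for exact-IOU constructions.
rect_mask <- function(H, W, rows, cols, label = 1L) {
  m <- matrix(0L, H, W)
  m[rows, cols] <- label
  m
}

# Instance-mask pair with a single gt/pred cell of exactly the given IOU,
# via two equal-size rectangles sharing part of their columns.
iou_pair <- function(iou) {
  if (iou == 0.6) {        # 4x4 vs 4x4 shifted one column: 12 / 20
    list(gt = rect_mask(12, 12, 2:5, 2:5),
         pred = rect_mask(12, 12, 2:5, 3:6))
  } else if (iou == 0.8) { # 5x9 vs 5x9 shifted one column: 40 / 50
    list(gt = rect_mask(16, 16, 2:6, 2:10),
         pred = rect_mask(16, 16, 2:6, 3:11))
  } else stop("no construction for this IOU")
}

# Exhaustive maximum one-to-one matching: the number of gt/pred pairs with
# IOU strictly above `thr` that can be matched simultaneously.
oracle_max_matching <- function(M, thr) {
  n_gt <- nrow(M); n_pred <- ncol(M)
  if (n_gt == 0L || n_pred == 0L) return(0L)
  best <- 0L
  recurse <- function(g, used) {
    if (g > n_gt) return(0L)
    res <- recurse(g + 1L, used)  # leave gt g unmatched
    for (p in seq_len(n_pred)) {
      if (!used[p] && M[g, p] > thr) {
        used2 <- used; used2[p] <- TRUE
        res <- max(res, 1L + recurse(g + 1L, used2))
      }
    }
    res
  }
  recurse(1L, logical(n_pred))
}

# Random gt/pred instance-mask pair with realistic disagreement: the
# prediction is the truth shifted a little, with occasional dropped cells
# and spurious blobs.
random_mask_pair <- function(seed) {
  set.seed(seed)
  s <- generate_sample(tiny_synth(), index = seed)
  gt <- s$mask
  K <- max(gt)
  pred_bin <- matrix(0L, nrow(gt), ncol(gt))
  for (k in seq_len(K)) {
    if (runif(1) < 0.15) next  # dropped cell
    dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
    px <- which(gt == k, arr.ind = TRUE)
    r2 <- pmin(pmax(px[, 1] + dr, 1L), nrow(gt))
    c2 <- pmin(pmax(px[, 2] + dc, 1L), ncol(gt))
    pred_bin[cbind(r2, c2)] <- 1L
  }
  if (runif(1) < 0.4) {  # spurious blob
    r0 <- sample(5:55, 1); c0 <- sample(5:55, 1)
    pred_bin[r0:(r0 + 4), c0:(c0 + 4)] <- 1L
  }
  list(gt = gt, pred = label_instances(pred_bin))
}

# 8 synthetic training patches at full 256x256 resolution (generator
# defaults), shared by the end-to-end tests.
smoke_patches <- function(n = 8L) {
  sc <- synth_config()
  samples <- lapply(seq_len(n), function(i) generate_sample(sc, i))
  list(samples = samples,
       patches = lapply(samples, function(s)
         list(image = s$image, mask = s$mask)))
}
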