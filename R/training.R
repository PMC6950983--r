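# Training: the -log Dice + binary cross-entropy objective, Adam
# optimisation with best-validation checkpointing, and the optional
# fine-tuning phase at a reduced learning rate.

#' Training configuration
#'
#' `lr` is the initial Adam learning rate (0.0005), `lambda_bce` the weight
#' of the binary cross-entropy term relative to the negative-log-Dice term
#' (1.0), `epochs` the number of main training epochs (20) and
#' `finetune_epochs`/`finetune_lr` the optional fine-tuning phase (5 epochs
#' at 0.0001).  `dice_smooth` is the small constant added to the numerator
#' and denominator of the soft Dice coefficient so that `-log D` stays
#' finite on empty intersections.  `bn_momentum` is the moving-average
#' momentum of the batch-normalisation statistics.
#'
#' @param lr initial learning rate, > 0.
#' @param lambda_bce weight of the cross-entropy term, >= 0.
#' @param epochs main training epochs.
#' @param finetune_epochs fine-tuning epochs.
#' @param finetune_lr fine-tuning learning rate.
#' @param batch_size mini-batch size.
#' @param seed integer seed (shuffling, initialisation).
#' @param dice_smooth smoothing constant, > 0.
#' @param bn_momentum batch-norm moving-average momentum in `[0, 1)`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 5e-4, lambda_bce = 1.0, epochs = 20L,
                         finetune_epochs = 5L, finetune_lr = 1e-4,
                         batch_size = 16L, seed = 0L, dice_smooth = 1e-6,
                         bn_momentum = 0.9) {
  stopifnot(lr > 0, lambda_bce >= 0, epochs >= 0, finetune_epochs >= 0,
            finetune_lr > 0, batch_size >= 1, dice_smooth > 0,
            bn_momentum >= 0, bn_momentum < 1)
  structure(list(lr = lr, lambda_bce = lambda_bce,
                 epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_lr = finetune_lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 dice_smooth = dice_smooth, bn_momentum = bn_momentum),
            class = "train_config")
}

#' Soft Dice coefficient
#'
#' `D = (2 |A n B| + s) / (|A| + |B| + s)` with the soft convention:
#' the intersection is the sum of element-wise products and the
#' cardinalities are plain sums, so probability maps are admitted on either
#' side.  For identical binary masks the value is 1 (up to the smoothing
#' constant); for disjoint masks it is `s / (|A| + |B| + s)`.
#'
#' @param y_true mask or probability map (values in `[0, 1]`).
#' @param y_pred probability map of the same shape.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar in `(0, 1]`.
#' @export
dice_coefficient <- function(y_true, y_pred, smooth = 1e-6) {
  if (!all(dim(y_true) == dim(y_pred)))
    stop("y_true and y_pred must have identical shapes")
  (2 * sum(y_true * y_pred) + smooth) / (sum(y_true) + sum(y_pred) + smooth)
}

#' Training objective
#'
#' `L = lambda_bce * BCE + (1/M) * sum_i -log D(y_true_i, y_pred_i)`:
#' the mean binary cross-entropy over all pixels of the batch plus the mean
#' over the M batch samples of the negative log soft Dice coefficient.
#' Predicted probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the
#' cross-entropy for numerical stability; the Dice smoothing constant keeps
#' the log finite when prediction and truth do not intersect.
#'
#' @param y_true_batch list of masks (or a single mask).
#' @param y_pred_batch list of probability maps (or a single map).
#' @param config a [train_config()].
#' @return scalar loss value.
#' @export
loss <- function(y_true_batch, y_pred_batch, config = train_config()) {
  if (!is.list(y_true_batch)) y_true_batch <- list(y_true_batch)
  if (!is.list(y_pred_batch)) y_pred_batch <- list(y_pred_batch)
  stopifnot(length(y_true_batch) == length(y_pred_batch))
  M <- length(y_true_batch)
  bce <- 0; nld <- 0
  for (i in seq_len(M)) {
    yt <- y_true_batch[[i]]; yp <- y_pred_batch[[i]]
    if (!all(dim(yt) == dim(yp))) stop("shape mismatch in batch element ", i)
    if (any(yp < 0 | yp > 1)) stop("probabilities outside [0, 1]")
    pc <- pmin(pmax(yp, 1e-7), 1 - 1e-7)
    bce <- bce - mean(yt * log(pc) + (1 - yt) * log(1 - pc)) / M
    nld <- nld - log(dice_coefficient(yt, yp, config$dice_smooth)) / M
  }
  config$lambda_bce * bce + nld
}

# Gradient of the objective w.r.t. the head pre-activation (logits); exact
# for the cross-entropy term, sigmoid-chained for the Dice term.
.loss_grad_preact <- function(y_true, y_pred, M, config) {
  s <- config$dice_smooth
  num <- 2 * sum(y_true * y_pred) + s
  den <- sum(y_true) + sum(y_pred) + s
  config$lambda_bce * (y_pred - y_true) / (length(y_pred) * M) +
    (1 / den - 2 * y_true / num) * y_pred * (1 - y_pred) / M
}

.patch_xy <- function(p) {
  if (inherits(p, "patch_record"))
    list(x = p$image_patch, y = p$mask_patch)
  else list(x = p$image, y = if (!is.null(p$mask)) (p$mask > 0) * 1 else NULL)
}

.l2_penalty <- function(model) {
  lam <- model$config$l2_lambda
  if (lam == 0) return(0)
  tot <- 0
  for (id in ls(model$params)) tot <- tot + sum(model$params[[id]]$W^2)
  lam * tot
}

.eval_loss <- function(model, patches, config) {
  if (length(patches) == 0L) return(NA_real_)
  tot <- 0
  bs <- config$batch_size
  idx <- seq_along(patches)
  nb <- 0L
  for (b in split(idx, ceiling(idx / bs))) {
    xy <- lapply(patches[b], .patch_xy)
    fw <- forward_pass(model, lapply(xy, `[[`, "x"), training = FALSE)
    preds <- lapply(fw$out, function(a) a[, , 1L])
    tot <- tot + loss(lapply(xy, `[[`, "y"), preds, config)
    nb <- nb + 1L
  }
  tot / nb + .l2_penalty(model)
}

#' Mean soft Dice of a model over a patch set
#'
#' Forward passes (inference mode) every patch and averages the soft Dice
#' coefficient between prediction and mask.
#'
#' @param model a `nucleiseg_model`.
#' @param patches list of patches.
#' @param smooth Dice smoothing constant.
#' @return mean Dice in `(0, 1]`.
#' @export
evaluate_dice <- function(model, patches, smooth = 1e-6) {
  mean(vapply(patches, function(p) {
    xy <- .patch_xy(p)
    dice_coefficient(xy$y, model_forward(model, xy$x), smooth)
  }, numeric(1)))
}

.run_training <- function(model, train_patches, val_patches, epochs, lr,
                          config, epoch_offset = 0L) {
  if (length(train_patches) == 0L) stop("empty training set")
  monitor <- if (length(val_patches) > 0L) val_patches else train_patches
  opt <- adam_init(model)
  best_loss <- .eval_loss(model, monitor, config)
  best_params <- .copy_params(model$params)
  lam <- model$config$l2_lambda
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(epochs)) {
    ord <- .with_stream(config$seed, 100L + epoch_offset + ep,
                        sample.int(length(train_patches)))
    ep_loss <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      xy <- lapply(train_patches[b], .patch_xy)
      xs <- lapply(xy, `[[`, "x")
      ys <- lapply(xy, `[[`, "y")
      fw <- forward_pass(model, xs, training = TRUE, keep_cache = TRUE,
                         momentum = config$bn_momentum)
      preds <- lapply(fw$out, function(a) a[, , 1L])
      ep_loss <- ep_loss + loss(ys, preds, config) + .l2_penalty(model)
      nb <- nb + 1L
      M <- length(b)
      gout <- lapply(seq_len(M), function(i) {
        g <- .loss_grad_preact(ys[[i]], preds[[i]], M, config)
        array(g, c(dim(g), 1L))
      })
      pg <- backward_pass(model, fw, gout, gout_is_preact = TRUE)
      if (lam > 0)
        for (id in names(pg))
          if (!is.null(pg[[id]]$W))
            pg[[id]]$W <- pg[[id]]$W + 2 * lam * model$params[[id]]$W
      opt <- adam_step(model, pg, opt, lr)
    }
    vl <- .eval_loss(model, monitor, config)
    hist <- rbind(hist, data.frame(epoch = epoch_offset + ep,
                                   train_loss = ep_loss / nb, val_loss = vl))
    if (!is.na(vl) && vl < best_loss) {
      best_loss <- vl
      best_params <- .copy_params(model$params)
    }
  }
  model$params <- best_params
  list(model = model, history = hist, best_val_loss = best_loss)
}

#' Train a model
#'
#' Adam optimisation of the [loss()] objective at `config$lr` for
#' `config$epochs` epochs.  The validation loss is evaluated after every
#' epoch and the parameters achieving the lowest validation loss are the
#' ones returned (best-checkpoint rule).  When `val_patches` is empty the
#' training set itself is monitored.
#'
#' @param model a `nucleiseg_model` (modified copy returned).
#' @param train_patches non-empty list of training patches (`patch_record`s
#'   or lists with `image`/`mask`).
#' @param val_patches list of validation patches (possibly empty).
#' @param config a [train_config()].
#' @return list with `model` (best checkpoint), `history` (data.frame of
#'   per-epoch train/validation losses) and `best_val_loss`.
#' @export
train <- function(model, train_patches, val_patches = list(),
                  config = train_config()) {
  stopifnot(inherits(model, "nucleiseg_model"))
  .run_training(model, train_patches, val_patches, config$epochs, config$lr,
                config)
}

#' Fine-tune a trained model
#'
#' Continues optimisation for `config$finetune_epochs` epochs at the reduced
#' learning rate `config$finetune_lr` (must not exceed the initial rate),
#' with a fresh optimiser state and the same best-validation checkpoint
#' rule; the incoming parameters count as the initial checkpoint, so
#' fine-tuning never increases the best validation loss.  Zero fine-tuning
#' epochs return the model unchanged.
#'
#' @inheritParams train
#' @return list with `model`, `history` and `best_val_loss`.
#' @export
finetune <- function(model, train_patches, val_patches = list(),
                     config = train_config()) {
  stopifnot(inherits(model, "nucleiseg_model"))
  if (config$finetune_lr > config$lr)
    stop("finetune_lr must not exceed the initial learning rate")
  if (config$finetune_epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(),
                                     train_loss = numeric(),
                                     val_loss = numeric()),
                best_val_loss = .eval_loss(
                  model,
                  if (length(val_patches)) val_patches else train_patches,
                  config)))
  .run_training(model, train_patches, val_patches, config$finetune_epochs,
                config$finetune_lr, config, epoch_offset = 1000L)
}
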