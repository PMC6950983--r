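# Network builders: the dense-encoder light-weight U-Net ("U-Net+") and the
# reference U-Net / nested U-Net (U-Net++) topologies, all assembled from the
# same block vocabulary (3x3 conv blocks, stride-2 down-sampling, 2x
# up-sampling by transposed convolution or row/column repetition, 1x1 sigmoid
# head).  Filters at level n are 2^(n-1) * base_filters.

#' Model configuration
#'
#' Describes one of the three segmentation architectures.  `base_filters` (B)
#' sets the channel width of the first level and must be a multiple of 2;
#' filters at level `n` are `2^(n-1) * B`.  `depth` (N) is the number of
#' resolution levels (the dense-encoder `unet_plus` wiring is defined for
#' `depth = 5`, the setting used throughout).  `upsample_mode` selects how the
#' decoder enlarges feature maps: a learnable 2x transposed convolution
#' (`"transposed_conv"`, which halves the channel count before the two
#' following conv blocks) or parameter-free repetition up-sampling
#' (`"upsample"`, which preserves channels).  `l2_lambda` is the L2
#' weight-decay coefficient applied to convolution kernels; by convention it
#' defaults to 1e-4 for `unet_pp` at `B = 16` and 0 otherwise.  `batch_norm`
#' controls whether conv and down-sampling blocks carry batch normalisation;
#' the default (`TRUE` for `unet_plus`, `FALSE` for the two reference
#' builders) reproduces the published per-architecture weight totals.
#'
#' @param arch one of `"unet_plus"`, `"unet"`, `"unet_pp"`.
#' @param base_filters number of filters in the first level (B), multiple of 2.
#' @param depth number of levels (N).
#' @param upsample_mode `"transposed_conv"` or `"upsample"`.
#' @param l2_lambda L2 regularisation coefficient for conv kernels (`NULL` =
#'   architecture-dependent default).
#' @param n_classes number of output channels (sigmoid probabilities).
#' @param batch_norm logical or `NULL` (architecture-dependent default).
#' @param input_size spatial size of the square input patch in pixels.
#' @return an object of class `model_config`.
#' @export
model_config <- function(arch = c("unet_plus", "unet", "unet_pp"),
                         base_filters = 16L, depth = 5L,
                         upsample_mode = c("transposed_conv", "upsample"),
                         l2_lambda = NULL, n_classes = 1L,
                         batch_norm = NULL, input_size = 256L) {
  arch <- match.arg(arch)
  upsample_mode <- match.arg(upsample_mode)
  base_filters <- as.integer(base_filters)
  depth <- as.integer(depth)
  if (base_filters < 2L || base_filters %% 2L != 0L)
    stop("base_filters must be a positive multiple of 2")
  if (depth < 2L) stop("depth must be >= 2")
  if (arch == "unet_plus" && depth != 5L)
    stop("the dense-encoder wiring of 'unet_plus' is defined for depth = 5")
  if (input_size %% 2L^(depth - 1L) != 0L)
    stop("input_size must be divisible by 2^(depth-1)")
  if (is.null(batch_norm)) batch_norm <- arch == "unet_plus"
  if (is.null(l2_lambda))
    l2_lambda <- if (arch == "unet_pp" && base_filters == 16L) 1e-4 else 0
  if (l2_lambda < 0) stop("l2_lambda must be >= 0")
  structure(list(arch = arch, base_filters = base_filters, depth = depth,
                 upsample_mode = upsample_mode, l2_lambda = l2_lambda,
                 n_classes = as.integer(n_classes),
                 batch_norm = isTRUE(batch_norm),
                 input_size = as.integer(input_size)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model_config: %s  B=%d  N=%d  %s  lambda=%g  bn=%s\n",
              x$arch, x$base_filters, x$depth, x$upsample_mode, x$l2_lambda,
              x$batch_norm))
  invisible(x)
}

# -- graph assembly helpers -------------------------------------------------

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$ch <- c(input = 1L)
  env$nodes[["input"]] <- list(id = "input", op = "input", inputs = character())
  env
}

.add <- function(g, id, op, inputs, filters = NA_integer_, k = NA_integer_,
                 stride = 1L, act = "linear", bn = FALSE) {
  cin <- unname(g$ch[inputs])
  out_ch <- switch(op,
    conv = filters, tconv = filters,
    maxpool = cin, upsample = cin,
    concat = sum(cin))
  g$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                        k = k, stride = stride, act = act, bn = bn,
                        filters = as.integer(filters),
                        cin = cin, in_channels = cin)
  g$ch[[id]] <- as.integer(out_ch)
  id
}

.conv <- function(g, id, input, filters, k = 3L, stride = 1L, act = "relu",
                  bn = FALSE)
  .add(g, id, "conv", input, filters, k, stride, act, bn)
.tconv <- function(g, id, input, filters, k = 2L)
  .add(g, id, "tconv", input, filters, k)
.pool <- function(g, id, input) .add(g, id, "maxpool", input)
.upsamp <- function(g, id, input) .add(g, id, "upsample", input)
.concat <- function(g, id, inputs) .add(g, id, "concat", inputs)

# Classic U-Net: two conv blocks per level, 2x2 max pooling, decoder by 2x2
# transposed convolution (channel-halving) or repeat-upsampling, skip
# concatenation, two conv blocks, 1x1 sigmoid head.
.build_unet <- function(g, cfg) {
  B <- cfg$base_filters; N <- cfg$depth; bn <- cfg$batch_norm
  f <- B * 2L^(seq_len(N) - 1L)
  prev <- "input"
  for (n in seq_len(N)) {
    .conv(g, sprintf("enc%d_1", n), prev, f[n], bn = bn)
    prev <- .conv(g, sprintf("enc%d_2", n), sprintf("enc%d_1", n), f[n], bn = bn)
    if (n < N) prev <- .pool(g, sprintf("pool%d", n), prev)
  }
  prev <- sprintf("enc%d_2", N)
  for (n in rev(seq_len(N - 1L))) {
    up <- if (cfg$upsample_mode == "transposed_conv")
      .tconv(g, sprintf("up%d", n), prev, f[n], k = 2L)
    else
      .upsamp(g, sprintf("up%d", n), prev)
    cc <- .concat(g, sprintf("cat%d", n), c(up, sprintf("enc%d_2", n)))
    .conv(g, sprintf("dec%d_1", n), cc, f[n], bn = bn)
    prev <- .conv(g, sprintf("dec%d_2", n), sprintf("dec%d_1", n), f[n], bn = bn)
  }
  .conv(g, "head", prev, cfg$n_classes, k = 1L, act = "sigmoid", bn = FALSE)
}

# Nested U-Net (U-Net++): U-Net backbone plus the dense grid of re-sampling
# nodes X[i,j]; each node concatenates all previous outputs of its level with
# the up-sampled deeper node and applies two conv blocks.  No deep
# supervision: the head reads X[1, N-1] only.
.build_unet_pp <- function(g, cfg) {
  B <- cfg$base_filters; N <- cfg$depth; bn <- cfg$batch_norm
  f <- B * 2L^(seq_len(N) - 1L)
  X <- matrix(NA_character_, N, N)
  prev <- "input"
  for (i in seq_len(N)) {
    .conv(g, sprintf("x%d0_1", i), prev, f[i], bn = bn)
    X[i, 1] <- .conv(g, sprintf("x%d0_2", i), sprintf("x%d0_1", i), f[i],
                     bn = bn)
    if (i < N) prev <- .pool(g, sprintf("pool%d", i), X[i, 1])
  }
  for (j in seq_len(N - 1L)) {
    for (i in seq_len(N - j)) {
      up <- if (cfg$upsample_mode == "transposed_conv")
        .tconv(g, sprintf("up%d_%d", i, j), X[i + 1L, j], f[i], k = 2L)
      else
        .upsamp(g, sprintf("up%d_%d", i, j), X[i + 1L, j])
      cc <- .concat(g, sprintf("cat%d_%d", i, j), c(X[i, seq_len(j)], up))
      .conv(g, sprintf("x%d%d_1", i, j), cc, f[i], bn = bn)
      X[i, j + 1L] <- .conv(g, sprintf("x%d%d_2", i, j),
                            sprintf("x%d%d_1", i, j), f[i], bn = bn)
    }
  }
  .conv(g, "head", X[1L, N], cfg$n_classes, k = 1L, act = "sigmoid",
        bn = FALSE)
}

# Dense-encoder U-Net+ (depth 5).  Encoder chains of conv blocks per level
# with lengths (5, 4, 2, 1); every chain block beyond the first concatenates
# the preceding block with a stride-2 down-sampling conv block from the level
# above (one down block per column).  The final down block of each level is
# shared between the next level's chain and a direct down-sampling pathway
# that carries that level's encoded features, unconvolved, to the decoder
# concatenations of the next two levels.  The decoder concatenation at level
# m gathers the deeper up-block output, the level-m chain output and the
# direct tensors, and is consumed by an up block (transposed conv 3x3 stride
# 2, or repeat-upsampling) followed by two conv blocks.
.build_unet_plus <- function(g, cfg) {
  B <- cfg$base_filters; bn <- cfg$batch_norm
  f <- B * 2L^(0:4)
  tc <- cfg$upsample_mode == "transposed_conv"
  # level-1 chain: c1_1 .. c1_5
  prev <- "input"
  for (j in 1:5)
    prev <- .conv(g, sprintf("c1_%d", j), prev, f[1], bn = bn)
  # down columns level 1 -> 2 (inputs c1_2 .. c1_5)
  for (j in 1:4)
    .conv(g, sprintf("d1_%d", j), sprintf("c1_%d", j + 1L), f[2],
          stride = 2L, bn = bn)
  # level-2 chain: c2_1 .. c2_4
  .conv(g, "c2_1", "d1_1", f[2], bn = bn)
  for (j in 2:4) {
    cc <- .concat(g, sprintf("cat2_%d", j),
                  c(sprintf("c2_%d", j - 1L), sprintf("d1_%d", j)))
    .conv(g, sprintf("c2_%d", j), cc, f[2], bn = bn)
  }
  # down columns level 2 -> 3 (inputs c2_3, c2_4)
  .conv(g, "d2_1", "c2_3", f[3], stride = 2L, bn = bn)
  .conv(g, "d2_2", "c2_4", f[3], stride = 2L, bn = bn)
  # direct pathway from level 1: d1_4 continued one level further down
  .conv(g, "e1_3", "d1_4", f[3], stride = 2L, bn = bn)
  # level-3 chain: c3_1, c3_2
  .conv(g, "c3_1", "d2_1", f[3], bn = bn)
  cc <- .concat(g, "cat3_2", c("c3_1", "d2_2"))
  .conv(g, "c3_2", cc, f[3], bn = bn)
  # down column level 3 -> 4 and direct pathway from level 2
  .conv(g, "d3_1", "c3_2", f[4], stride = 2L, bn = bn)
  .conv(g, "e2_4", "d2_2", f[4], stride = 2L, bn = bn)
  # level-4 chain: c4_1, then the level-5 down block (no bottleneck convs)
  .conv(g, "c4_1", "d3_1", f[4], bn = bn)
  .conv(g, "d4_1", "c4_1", f[5], stride = 2L, bn = bn)
  # decoder
  up_block <- function(lvl, input, extra) {
    upid <- if (tc)
      .tconv(g, sprintf("up%d", lvl), input, f[lvl], k = 3L)
    else
      .upsamp(g, sprintf("up%d", lvl), input)
    .conv(g, sprintf("r%d_1", lvl), upid, f[lvl], bn = bn)
    .conv(g, sprintf("r%d_2", lvl), sprintf("r%d_1", lvl), f[lvl], bn = bn)
    if (is.null(extra)) return(sprintf("r%d_2", lvl))
    .concat(g, sprintf("dcat%d", lvl), c(sprintf("r%d_2", lvl), extra))
  }
  c4 <- up_block(4L, "d4_1", c("c4_1", "e2_4", "d3_1"))
  c3 <- up_block(3L, c4, c("c3_2", "e1_3", "d2_2"))
  c2 <- up_block(2L, c3, c("c2_4", "d1_4"))
  c1 <- up_block(1L, c2, NULL)
  .conv(g, "head", c1, cfg$n_classes, k = 1L, act = "sigmoid", bn = FALSE)
}

.init_params <- function(g) {
  params <- new.env(parent = emptyenv())
  for (node in g$nodes) {
    if (!node$op %in% c("conv", "tconv")) next
    k <- node$k; cin <- node$cin; f <- node$filters
    limit <- sqrt(6 / (k * k * cin + k * k * f))
    p <- list(
      W = if (node$op == "conv")
        matrix(runif(k * k * cin * f, -limit, limit), k * k * cin, f)
      else
        matrix(runif(k * k * f * cin, -limit, limit), k * k * f, cin),
      b = numeric(f))
    if (isTRUE(node$bn)) {
      p$gamma <- rep(1, f); p$beta <- numeric(f)
      p$rmean <- numeric(f); p$rvar <- rep(1, f)
    }
    params[[node$id]] <- p
  }
  params
}

#' Build a segmentation model
#'
#' Assembles the block graph for the configured architecture and initialises
#' its parameters (Glorot-uniform kernels, zero biases, unit batch-norm
#' scales).
#'
#' @param config a [model_config()].
#' @param seed optional integer; when given, initialisation is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an object of class `nucleiseg_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  g <- .new_builder()
  switch(config$arch,
         unet = .build_unet(g, config),
         unet_pp = .build_unet_pp(g, config),
         unet_plus = .build_unet_plus(g, config))
  params <- if (is.null(seed)) .init_params(g)
  else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    .init_params(g)
  }
  structure(list(config = config, graph = g$nodes, channels = g$ch,
                 params = params, output_id = "head"),
            class = "nucleiseg_model")
}

#' @export
print.nucleiseg_model <- function(x, ...) {
  cat(sprintf("nucleiseg_model: %s  B=%d  N=%d  %s  %s weights\n",
              x$config$arch, x$config$base_filters, x$config$depth,
              x$config$upsample_mode,
              format(count_weights(x), big.mark = ",")))
  invisible(x)
}

#' Total number of model parameters
#'
#' Counts every stored parameter: convolution and transposed-convolution
#' kernels, biases, and all four batch-normalisation parameter vectors per
#' normalised block (scale, shift, moving mean, moving variance) -- the
#' framework-total convention used when model sizes are reported in millions.
#'
#' @param model a `nucleiseg_model`.
#' @return integer parameter count.
#' @export
count_weights <- function(model) {
  stopifnot(inherits(model, "nucleiseg_model"))
  tot <- 0L
  for (id in ls(model$params))
    tot <- tot + sum(vapply(model$params[[id]], length, 1L))
  tot
}

#' Per-block architecture summary
#'
#' Lists every block of the architecture with its output shape (at the
#' configured input size), its input blocks and its parameter count.  The
#' parameter column sums exactly to [count_weights()].
#'
#' @param config a [model_config()] or an already built `nucleiseg_model`.
#' @return a `data.frame` with columns `block`, `op`, `output_shape`,
#'   `inputs`, `n_params`.
#' @export
summarize_architecture <- function(config) {
  model <- if (inherits(config, "nucleiseg_model")) config
  else build_model(config, seed = 0L)
  sz <- model$config$input_size
  shape <- c(input = sz)
  rows <- lapply(model$graph, function(node) {
    s_in <- if (length(node$inputs)) shape[[node$inputs[1L]]] else sz
    s_out <- switch(node$op,
      input = sz,
      conv = if (node$stride == 2L) ceiling(s_in / 2L) else s_in,
      tconv = s_in * 2L,
      maxpool = s_in %/% 2L,
      upsample = s_in * 2L,
      concat = s_in)
    shape[[node$id]] <<- s_out
    np <- if (!is.null(model$params[[node$id]]))
      sum(vapply(model$params[[node$id]], length, 1L)) else 0L
    kk <- if (!is.null(node$k) && !is.na(node$k))
      sprintf("%dx%d", node$k, node$k) else ""
    data.frame(block = node$id,
               op = paste0(node$op, if (nzchar(kk)) paste0(" ", kk) else ""),
               output_shape = sprintf("%dx%dx%d", s_out, s_out,
                                      model$channels[[node$id]]),
               inputs = paste(node$inputs, collapse = "+"),
               n_params = np)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward pass on a single image patch
#'
#' Runs the network in inference mode (batch-norm uses moving statistics) on
#' one patch and returns the sigmoid probability map.
#'
#' @param model a `nucleiseg_model`.
#' @param x numeric matrix (H x W) or array (H x W x 1) with values in
#'   `[0, 1]`.
#' @return probability matrix of the same spatial size.
#' @export
model_forward <- function(model, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  fw <- forward_pass(model, list(x), training = FALSE)
  out <- fw$out[[1L]]
  if (dim(out)[3L] == 1L) out <- out[, , 1L]
  out
}

#' Save / load model checkpoints
#'
#' Checkpoints are plain RDS files holding the configuration and a list copy
#' of all parameter arrays.
#'
#' @param model a `nucleiseg_model`.
#' @param path file path.
#' @return `load_model` returns the restored `nucleiseg_model`.
#' @export
save_model <- function(model, path) {
  plist <- lapply(ls(model$params), function(id) model$params[[id]])
  names(plist) <- ls(model$params)
  saveRDS(list(config = model$config, params = plist), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config, seed = 0L)
  for (id in names(obj$params)) model$params[[id]] <- obj$params[[id]]
  model
}

# Deep-copy the parameter environment (used for checkpointing during training).
.copy_params <- function(params) {
  out <- new.env(parent = emptyenv())
  for (id in ls(params)) out[[id]] <- params[[id]]
  out
}
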