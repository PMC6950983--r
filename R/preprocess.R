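# Image preprocessing front end: contrast-limited adaptive histogram
# equalisation (CLAHE), edge-preserving total-variation denoising, and
# rescaling to [0, 1].  The same pipeline is used for training and inference.

#' Preprocessing configuration
#'
#' `clahe_clip_limit` is the normalised histogram clip limit (fraction of the
#' per-tile pixel count; 0.01 is the common default) and `clahe_tile_grid`
#' the number of contextual tiles in rows and columns.  `tv_weight` is the
#' denoising weight of the Chambolle total-variation algorithm (larger =
#' smoother; 0 disables denoising exactly).  `enabled_stages` selects which
#' stages run; their order is fixed to CLAHE, then TV denoising, then
#' rescaling.
#'
#' @param clahe_clip_limit normalised clip limit, > 0.
#' @param clahe_tile_grid integer `(rows, cols)` tile grid.
#' @param tv_weight total-variation weight, >= 0.
#' @param enabled_stages subset of `c("clahe", "tv", "rescale")`.
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(clahe_clip_limit = 0.01,
                           clahe_tile_grid = c(8L, 8L),
                           tv_weight = 0.1,
                           enabled_stages = c("clahe", "tv", "rescale")) {
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be > 0")
  if (tv_weight < 0) stop("tv_weight must be >= 0")
  enabled_stages <- match.arg(enabled_stages,
                              c("clahe", "tv", "rescale"), several.ok = TRUE)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 tv_weight = tv_weight,
                 enabled_stages = enabled_stages),
            class = "preproc_config")
}

.check_img <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a 2-D numeric image matrix")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Local contrast enhancement on `clahe_tile_grid` tiles with the clip limit
#' preventing noise over-amplification.  Deterministic; output has the same
#' shape as the input.
#'
#' @param img 2-D numeric matrix, values in `[0, 1]`.
#' @param config a [preproc_config()].
#' @return enhanced image matrix.
#' @export
apply_clahe <- function(img, config = preproc_config()) {
  .check_img(img)
  x <- pmin(pmax(img, 0), 1)
  bins <- 256L
  out <- EBImage::clahe(x,
                        nx = config$clahe_tile_grid[2L],
                        ny = config$clahe_tile_grid[1L],
                        bins = bins,
                        limit = max(config$clahe_clip_limit * bins, 1))
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# Total variation (anisotropic sum of absolute forward differences); used by
# tests to verify that denoising decreases TV.
#' @rdname apply_tv_denoise
#' @export
total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}

#' Total-variation denoising (Chambolle dual projection)
#'
#' Minimises `||u - img||^2 / (2 * weight) + TV(u)` by Chambolle's
#' fixed-point iteration on the dual variable.  Edges are preserved while
#' oscillatory noise is removed; `tv_weight = 0` returns the input
#' unchanged.
#'
#' @param img 2-D numeric matrix.
#' @param config a [preproc_config()] (uses `tv_weight`).
#' @param n_iter_max maximum number of dual iterations.
#' @param eps relative dual-energy stopping tolerance.
#' @return denoised image matrix.
#' @export
apply_tv_denoise <- function(img, config = preproc_config(),
                             n_iter_max = 200L, eps = 2e-4) {
  .check_img(img)
  weight <- config$tv_weight
  if (weight < 0) stop("tv_weight must be >= 0")
  if (weight == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  p1 <- matrix(0, H, W)  # dual component along rows
  p2 <- matrix(0, H, W)  # dual component along columns
  d <- matrix(0, H, W)
  tau <- 0.25
  E_init <- 0; E_prev <- 0
  for (i in seq_len(n_iter_max)) {
    if (i > 1L) {
      d <- -(p1 + p2)
      d[-1L, ] <- d[-1L, ] + p1[-H, ]
      d[, -1L] <- d[, -1L] + p2[, -W]
      out <- img + d
    } else out <- img
    E <- if (i > 1L) sum(d^2) else 0
    g1 <- matrix(0, H, W); g2 <- matrix(0, H, W)
    g1[-H, ] <- out[-1L, ] - out[-H, ]
    g2[, -W] <- out[, -1L] - out[, -W]
    nrm <- sqrt(g1^2 + g2^2)
    E <- E + weight * sum(nrm)
    nrm <- nrm * (tau / weight) + 1
    p1 <- (p1 - tau * g1) / nrm
    p2 <- (p2 - tau * g2) / nrm
    E <- E / length(img)
    if (i == 1L) {
      E_init <- E; E_prev <- E
    } else {
      if (abs(E_prev - E) < eps * E_init) break
      E_prev <- E
    }
  }
  out
}

#' Rescale image intensities to \[0, 1\]
#'
#' Monotone affine map of the observed range onto `[0, 1]`; a constant image
#' maps to all zeros (degenerate-case convention).  Idempotent.
#'
#' @param img 2-D numeric matrix with at least one pixel.
#' @return rescaled image matrix.
#' @export
rescale01 <- function(img) {
  .check_img(img)
  r <- range(img)
  if (r[1L] == r[2L]) return(matrix(0, nrow(img), ncol(img)))
  (img - r[1L]) / (r[2L] - r[1L])
}

#' Full preprocessing pipeline
#'
#' Applies, in fixed order, the stages enabled in the configuration:
#' CLAHE, total-variation denoising, rescaling to `[0, 1]`.
#'
#' @param img 2-D numeric matrix.
#' @param config a [preproc_config()].
#' @return preprocessed image matrix.
#' @export
preprocess <- function(img, config = preproc_config()) {
  .check_img(img)
  out <- img
  if ("clahe" %in% config$enabled_stages) out <- apply_clahe(out, config)
  if ("tv" %in% config$enabled_stages) out <- apply_tv_denoise(out, config)
  if ("rescale" %in% config$enabled_stages) out <- rescale01(out)
  out
}
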