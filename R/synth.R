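# Synthetic microscopy-like nuclei images with instance ground truth.
# Emulates grey-scale bright/dark-field nuclei data: elliptical blobs with
# per-nucleus intensity and softly blurred edges, a non-uniform background
# illumination field, and additive Gaussian noise.

#' Synthetic data configuration
#'
#' Parameters of the nuclei image simulator.  Nuclei are filled rotated
#' ellipses with semi-axes drawn from `radius_range` (pixels, minimum 2) and
#' per-nucleus intensity from `nucleus_intensity_range`.  The background sits
#' at `background_level` plus a linear illumination gradient of amplitude
#' `illumination_gradient_amplitude` in a random direction, emulating the
#' uneven illumination of real microscopy fields.  A small Gaussian blur
#' softens nucleus boundaries (mimicking out-of-focus edges) before Gaussian
#' pixel noise of standard deviation `noise_sigma` is added.  All intensity
#' parameters live in `[0, 1]`.  With `allow_touching = FALSE` distinct
#' nuclei are separated by at least one background pixel (also diagonally).
#'
#' Identical configurations (including `seed`) produce bit-identical samples.
#'
#' @param image_height,image_width image size in pixels.
#' @param n_nuclei_range integer vector `(min, max)` nucleus count.
#' @param radius_range `(min, max)` ellipse semi-axis in pixels, min >= 2.
#' @param nucleus_intensity_range `(lo, hi)` nucleus intensity in `[0, 1]`.
#' @param background_level base background intensity in `[0, 1]`.
#' @param illumination_gradient_amplitude amplitude of the linear background
#'   illumination gradient in `[0, 1]`.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param allow_touching logical; may nuclei touch each other?
#' @param seed integer master seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_height = 256L, image_width = 256L,
                         n_nuclei_range = c(10L, 15L),
                         radius_range = c(8, 12),
                         nucleus_intensity_range = c(0.55, 0.95),
                         background_level = 0.15,
                         illumination_gradient_amplitude = 0.10,
                         noise_sigma = 0.02,
                         allow_touching = FALSE,
                         seed = 42L) {
  stopifnot(image_height >= 1, image_width >= 1,
            length(n_nuclei_range) == 2L, n_nuclei_range[1] >= 0,
            n_nuclei_range[1] <= n_nuclei_range[2],
            length(radius_range) == 2L, radius_range[1] <= radius_range[2])
  if (radius_range[1] < 2)
    stop("radius_range minimum must be >= 2 pixels")
  rng_ok <- function(x) all(x >= 0 & x <= 1)
  if (!rng_ok(nucleus_intensity_range) || !rng_ok(background_level) ||
      !rng_ok(illumination_gradient_amplitude))
    stop("intensity parameters must lie within [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_nuclei_range = as.integer(n_nuclei_range),
                 radius_range = as.numeric(radius_range),
                 nucleus_intensity_range = as.numeric(nucleus_intensity_range),
                 background_level = background_level,
                 illumination_gradient_amplitude =
                   illumination_gradient_amplitude,
                 noise_sigma = noise_sigma,
                 allow_touching = isTRUE(allow_touching),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One independent RNG stream per (seed, index) pair so any sample can be
# regenerated without generating its predecessors.
.with_stream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
             2147483399)
  force(expr)
}

.render_ellipse <- function(H, W, cy, cx, a, b, theta) {
  ry <- seq(max(1L, floor(cy - max(a, b) - 1)), min(H, ceiling(cy + max(a, b) + 1)))
  rx <- seq(max(1L, floor(cx - max(a, b) - 1)), min(W, ceiling(cx + max(a, b) + 1)))
  yy <- outer(ry - cy, rep(1, length(rx)))
  xx <- outer(rep(1, length(ry)), rx - cx)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = as.vector(row(inside))[inside] + ry[1L] - 1L,
        col = as.vector(col(inside))[inside] + rx[1L] - 1L)
}

#' Generate one synthetic sample
#'
#' Draws the nucleus count, places non-overlapping rotated ellipses by
#' rejection sampling, renders the intensity image and the instance label
#' mask.  Labels are contiguous `1..K` in placement order and every labelled
#' region is 4-connected.  The returned image is quantised to 8-bit grey
#' levels so that a written PNG round-trips exactly.
#'
#' @param config a [synth_config()].
#' @param index sample index (>= 1); each index has its own RNG stream.
#' @return a list with elements `image` (numeric matrix in `[0, 1]`) and
#'   `mask` (integer instance label matrix, 0 = background).
#' @export
generate_sample <- function(config, index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$image_height; W <- config$image_width
  .with_stream(config$seed, index, {
    K <- if (config$n_nuclei_range[1] == config$n_nuclei_range[2])
      config$n_nuclei_range[1]
    else sample(config$n_nuclei_range[1]:config$n_nuclei_range[2], 1L)
    mask <- matrix(0L, H, W)
    occupied <- matrix(FALSE, H, W)  # foreground dilated by 1 px
    placed <- 0L
    tries <- 0L
    max_tries <- 120L * max(K, 1L)
    while (placed < K) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf(
          "placement error: only %d of %d nuclei placed after %d attempts",
          placed, K, max_tries))
      a <- runif(1, config$radius_range[1], config$radius_range[2])
      b <- runif(1, config$radius_range[1], config$radius_range[2])
      theta <- runif(1, 0, pi)
      cy <- runif(1, 1 + b, H - b)
      cx <- runif(1, 1 + a, W - a)
      px <- .render_ellipse(H, W, cy, cx, a, b, theta)
      if (nrow(px) == 0L) next
      idx <- (px[, "col"] - 1L) * H + px[, "row"]
      clash <- if (config$allow_touching) any(mask[idx] > 0L)
      else any(occupied[idx])
      if (clash) next
      placed <- placed + 1L
      mask[idx] <- placed
      if (!config$allow_touching) {
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- pmin(pmax(px[, "row"] + dr, 1L), H)
          c2 <- pmin(pmax(px[, "col"] + dc, 1L), W)
          occupied[(c2 - 1L) * H + r2] <- TRUE
        }
      }
    }
    # intensity image: background + illumination gradient + nuclei
    ang <- runif(1, 0, 2 * pi)
    yn <- (row(mask) - 0.5) / H - 0.5
    xn <- (col(mask) - 0.5) / W - 0.5
    img <- config$background_level +
      config$illumination_gradient_amplitude * (cos(ang) * xn + sin(ang) * yn)
    if (K > 0) {
      ints <- runif(K, config$nucleus_intensity_range[1],
                    config$nucleus_intensity_range[2])
      fg <- mask > 0L
      img[fg] <- ints[mask[fg]]
    }
    img <- EBImage::gblur(img, sigma = 1)
    if (config$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, config$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255  # 8-bit quantisation, PNG round-trip exact
    list(image = matrix(img, H, W), mask = mask)
  })
}

#' Generate a dataset on disk
#'
#' Writes `n_images` samples in the stage-1 contest layout consumed by
#' [load_dataset()]: `out_dir/<id>/images/<id>.png` plus one binary PNG per
#' instance under `out_dir/<id>/masks/<id>_<k>.png` (8-bit grey-scale).
#'
#' @param config a [synth_config()].
#' @param n_images number of samples (>= 0).
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a manifest `data.frame` with one row per sample:
#'   `sample_id`, `image_path`, `n_instances`.
#' @export
generate_dataset <- function(config, n_images, out_dir) {
  stopifnot(inherits(config, "synth_config"), n_images >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- generate_sample(config, i)
    id <- sprintf("synth_%04d", i)
    img_dir <- file.path(out_dir, id, "images")
    msk_dir <- file.path(out_dir, id, "masks")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
    img_path <- file.path(img_dir, paste0(id, ".png"))
    png::writePNG(s$image, img_path)
    K <- max(s$mask, 0L)
    for (k in seq_len(K))
      png::writePNG((s$mask == k) * 1,
                    file.path(msk_dir, sprintf("%s_%03d.png", id, k)))
    rows[[i]] <- data.frame(sample_id = id, image_path = img_path,
                            n_instances = K, stringsAsFactors = FALSE)
  }
  manifest <- if (n_images > 0) do.call(rbind, rows)
  else data.frame(sample_id = character(), image_path = character(),
                  n_instances = integer(), stringsAsFactors = FALSE)
  invisible(manifest)
}
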