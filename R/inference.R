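# Whole-image inference: preprocessing, grid decomposition into patches,
# per-patch forward passes, overlap-max probability fusion, thresholding and
# morphological cleanup, and connected-component instance labelling.

#' Post-processing configuration
#'
#' Predictions are binarised at `prob_threshold` (strictly greater than);
#' connected foreground components smaller than `min_object_area` pixels are
#' removed and enclosed background holes smaller than `max_hole_area` pixels
#' are filled.  The defaults (0.5 and a few hundred pixels) target isolated
#' speckles and pinholes left by the pixel-wise classifier.
#'
#' @param prob_threshold probability threshold in `(0, 1)`.
#' @param min_object_area minimal object area in pixels, >= 0.
#' @param max_hole_area maximal hole area to fill in pixels, >= 0.
#' @return an object of class `postproc_config`.
#' @export
postproc_config <- function(prob_threshold = 0.5, min_object_area = 300L,
                            max_hole_area = 300L) {
  stopifnot(prob_threshold > 0, prob_threshold < 1,
            min_object_area >= 0, max_hole_area >= 0)
  structure(list(prob_threshold = prob_threshold,
                 min_object_area = as.integer(min_object_area),
                 max_hole_area = as.integer(max_hole_area)),
            class = "postproc_config")
}

#' Whole-image probability prediction
#'
#' Preprocesses the image (when a [preproc_config()] is given), decomposes
#' it into patches with [grid_patches()], forward passes every patch and
#' fuses the per-patch probabilities back into an image-sized map.  Pixels
#' covered by a single patch keep that patch's output; pixels inside
#' overlapping boundary re-crops receive the maximum over all covering
#' patches.  Zero padding used for small images is cropped away, so the
#' output always matches the input shape.
#'
#' @param model a `nucleiseg_model`.
#' @param image numeric image matrix.
#' @param preproc a [preproc_config()], or `NULL` to skip preprocessing.
#' @param grid a [patch_grid_config()]; defaults to the model's input size.
#' @return probability matrix with the shape of `image`.
#' @export
predict_image <- function(model, image, preproc = NULL, grid = NULL) {
  if (is.null(dim(image)) || any(dim(image) == 0L)) stop("empty image")
  if (is.null(grid))
    grid <- patch_grid_config(patch_size = model$config$input_size)
  if (grid$patch_size != model$config$input_size)
    stop("patch size does not match the model input size")
  if (!is.null(preproc)) image <- preprocess(image, preproc)
  H <- nrow(image); W <- ncol(image)
  patches <- grid_patches(image, mask = NULL, config = grid)
  prob <- matrix(-Inf, H, W)
  for (p in patches) {
    pr <- model_forward(model, p$image_patch)
    rr <- seq.int(p$row0 + 1L, min(p$row0 + grid$patch_size, H))
    cc <- seq.int(p$col0 + 1L, min(p$col0 + grid$patch_size, W))
    prob[rr, cc] <- pmax(prob[rr, cc], pr[seq_along(rr), seq_along(cc)])
  }
  prob
}

#' Binarise and morphologically clean a probability map
#'
#' Thresholds at `prob_threshold` (strict), removes 8-connected foreground
#' components with area below `min_object_area`, then fills 4-connected
#' background holes (components not touching the image border) with area
#' below `max_hole_area`.  The operation is idempotent.
#'
#' @param prob probability matrix with values in `[0, 1]`.
#' @param config a [postproc_config()].
#' @return binary integer matrix.
#' @export
binarize_and_clean <- function(prob, config = postproc_config()) {
  if (any(prob[is.finite(prob)] < 0) || any(prob > 1))
    stop("probabilities outside [0, 1]")
  bw <- (prob > config$prob_threshold) * 1L
  # remove small isolated objects (8-connected)
  if (config$min_object_area > 0L && any(bw == 1L)) {
    lab <- cc_label(bw, 8L)
    K <- max(lab)
    if (K > 0L) {
      areas <- tabulate(lab[lab > 0L], nbins = K)
      drop <- which(areas < config$min_object_area)
      if (length(drop)) bw[lab %in% drop] <- 0L
    }
  }
  # fill small enclosed holes (4-connected background)
  if (config$max_hole_area > 0L && any(bw == 0L)) {
    bg <- 1L - bw
    lab <- cc_label(bg, 4L)
    K <- max(lab)
    if (K > 0L) {
      border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                         lab[, ncol(lab)]))
      areas <- tabulate(lab[lab > 0L], nbins = K)
      fill <- setdiff(which(areas < config$max_hole_area), border)
      if (length(fill)) bw[lab %in% fill] <- 1L
    }
  }
  bw
}

#' Label connected components as instances
#'
#' Connected-component labelling of a binary mask; each connected region is
#' one predicted cell.  Labels are contiguous `1..K`.
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer instance label matrix.
#' @export
label_instances <- function(mask, connectivity = 8L) {
  if (!all(mask %in% c(0, 1))) stop("label_instances expects a binary mask")
  cc_label(matrix(as.integer(mask), nrow(mask), ncol(mask)),
           as.integer(connectivity))
}

#' Segment a whole image into nucleus instances
#'
#' Convenience wrapper chaining [predict_image()], [binarize_and_clean()]
#' and [label_instances()].
#'
#' @inheritParams predict_image
#' @param postproc a [postproc_config()].
#' @return list with `prob` (probability map), `mask` (cleaned binary mask)
#'   and `instances` (instance label matrix).
#' @export
segment_image <- function(model, image, preproc = NULL, grid = NULL,
                          postproc = postproc_config()) {
  prob <- predict_image(model, image, preproc, grid)
  mask <- binarize_and_clean(prob, postproc)
  list(prob = prob, mask = mask, instances = label_instances(mask))
}
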