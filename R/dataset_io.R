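# Dataset input/output in the Kaggle Data Science Bowl 2018 stage-1 layout:
# one directory per sample with images/<id>.png and masks/<instance>.png,
# plus the contest's column-major run-length mask encoding.

.read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  a
}

.channels_equal <- function(a) {
  if (length(dim(a)) == 2L) return(TRUE)
  nc <- dim(a)[3L]
  if (nc == 1L) return(TRUE)
  for (k in 2L:min(nc, 3L))
    if (any(a[, , k] != a[, , 1L])) return(FALSE)
  TRUE
}

.to_gray <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nc <- dim(a)[3L]
  if (nc == 1L) return(a[, , 1L])
  # luminance for RGB(A); alpha ignored
  0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
}

#' Load a dataset in the stage-1 contest layout
#'
#' Walks `root`, expecting one sub-directory per sample containing an
#' `images/` directory with a single PNG/TIFF and (unless
#' `with_masks = FALSE`) a `masks/` directory with one binary image per
#' nucleus instance.  Per-instance masks are merged into a single instance
#' label map, labels assigned in lexicographic file-name order.  Overlapping
#' instance masks raise an error naming the offending sample.
#'
#' When `grayscale_only = TRUE`, samples whose image channels are not
#' pixel-wise identical (i.e. genuinely coloured images) are excluded --
#' the deterministic reading of "grey-scale images only".
#'
#' @param root dataset root directory.
#' @param grayscale_only drop coloured samples?
#' @param with_masks require and read instance masks?
#' @return a list of sample records, each a list with `sample_id`, `image`
#'   (numeric matrix in `[0, 1]`) and `instances` (integer label matrix; all
#'   zeros when `with_masks = FALSE`).
#' @export
load_dataset <- function(root, grayscale_only = TRUE, with_masks = TRUE) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  ids <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  out <- list()
  for (id in ids) {
    img_dir <- file.path(root, id, "images")
    imgs <- sort(list.files(img_dir, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
    if (length(imgs) == 0L) stop("no image found for sample ", id)
    raw <- .read_gray(imgs[1L])
    if (grayscale_only && !.channels_equal(raw)) next
    image <- .to_gray(raw)
    H <- nrow(image); W <- ncol(image)
    instances <- matrix(0L, H, W)
    if (with_masks) {
      msk_dir <- file.path(root, id, "masks")
      if (!dir.exists(msk_dir)) stop("missing masks directory for sample ", id)
      mfiles <- sort(list.files(msk_dir, pattern = "\\.png$",
                                ignore.case = TRUE, full.names = TRUE))
      for (k in seq_along(mfiles)) {
        m <- .to_gray(.read_gray(mfiles[k])) > 0.5
        if (!all(dim(m) == c(H, W)))
          stop("mask size mismatch in sample ", id)
        if (any(instances[m] != 0L))
          stop("overlapping instance masks in sample ", id)
        instances[m] <- k
      }
    }
    out[[length(out) + 1L]] <- list(sample_id = id, image = image,
                                    instances = instances)
  }
  out
}

#' Run-length encode a binary mask (contest dialect)
#'
#' Pixels are numbered 1-based in column-major order (top-to-bottom, then
#' left-to-right); runs are maximal `(start, length)` pairs over foreground
#' pixels, sorted ascending.
#'
#' @param mask binary (0/1 or logical) matrix.
#' @return an object of class `rle_mask`: list with `height`, `width` and a
#'   two-column integer matrix `runs` (`start`, `length`).
#' @export
rle_encode <- function(mask) {
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1)))
    stop("rle_encode expects a binary mask")
  r <- rle(as.integer(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  runs <- cbind(start = starts[keep], length = r$lengths[keep])
  structure(list(height = nrow(mask), width = ncol(mask),
                 runs = matrix(as.integer(runs), ncol = 2L,
                               dimnames = list(NULL, c("start", "length")))),
            class = "rle_mask")
}

#' Decode a run-length mask
#'
#' @param rle an `rle_mask` (or list with `height`, `width`, `runs`).
#' @return binary integer matrix of size `height` x `width`.
#' @export
rle_decode <- function(rle) {
  H <- rle$height; W <- rle$width
  runs <- rle$runs
  v <- integer(H * W)
  if (!is.null(runs) && nrow(runs) > 0L) {
    if (any(runs[, 1L] < 1L) || any(runs[, 2L] < 1L))
      stop("invalid run-length data")
    if (nrow(runs) > 1L) {
      if (any(diff(runs[, 1L]) <= 0))
        stop("runs must be sorted ascending by start")
      if (any(runs[-nrow(runs), 1L] + runs[-nrow(runs), 2L] > runs[-1L, 1L]))
        stop("overlapping runs")
    }
    if (any(runs[, 1L] + runs[, 2L] - 1L > H * W))
      stop("run exceeds image area")
    for (i in seq_len(nrow(runs)))
      v[runs[i, 1L]:(runs[i, 1L] + runs[i, 2L] - 1L)] <- 1L
  }
  matrix(v, H, W)
}

#' Read / write contest run-length CSV files
#'
#' The CSV has columns `ImageId` and `EncodedPixels` (space-separated
#' start/length pairs), one row per instance.
#'
#' @param path CSV file path.
#' @return `read_rle_csv` returns a `data.frame` with columns `ImageId`,
#'   `EncodedPixels`.
#' @export
read_rle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("ImageId", "EncodedPixels") %in% names(df)))
    stop("RLE CSV must have columns ImageId and EncodedPixels")
  df
}

#' @rdname read_rle_csv
#' @param df data.frame with `ImageId`, `EncodedPixels`.
#' @export
write_rle_csv <- function(df, path) {
  utils::write.csv(df[, c("ImageId", "EncodedPixels")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between instance masks and run-length rows
#'
#' `instances_to_rle` encodes each label of an instance mask as one
#' `EncodedPixels` string; `rle_to_instances` merges the rows of one sample
#' back into an instance label map (labels in row order, overlap is an
#' error).
#'
#' @param instances integer instance label matrix.
#' @param sample_id sample identifier for the `ImageId` column.
#' @return `instances_to_rle`: data.frame with one row per instance.
#' @export
instances_to_rle <- function(instances, sample_id) {
  K <- max(instances, 0L)
  enc <- vapply(seq_len(K), function(k) {
    r <- rle_encode((instances == k) * 1L)
    paste(t(r$runs), collapse = " ")
  }, character(1))
  data.frame(ImageId = rep(sample_id, K), EncodedPixels = enc,
             stringsAsFactors = FALSE)
}

#' @rdname instances_to_rle
#' @param rows data.frame rows (`ImageId`, `EncodedPixels`) of one sample.
#' @param height,width mask dimensions in pixels.
#' @export
rle_to_instances <- function(rows, height, width) {
  instances <- matrix(0L, height, width)
  for (i in seq_len(nrow(rows))) {
    nums <- as.integer(strsplit(trimws(rows$EncodedPixels[i]), "\\s+")[[1L]])
    if (length(nums) %% 2L != 0L) stop("malformed EncodedPixels")
    runs <- matrix(nums, ncol = 2L, byrow = TRUE,
                   dimnames = list(NULL, c("start", "length")))
    m <- rle_decode(list(height = height, width = width, runs = runs))
    if (any(instances[m == 1L] != 0L))
      stop("overlapping run-length instances for ", rows$ImageId[i])
    instances[m == 1L] <- i
  }
  instances
}
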