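# Instance-level evaluation: per-cell IOU matching against ground truth,
# AP50:95-style precision, and dataset aggregation.

#' Evaluation configuration
#'
#' `thresholds` is the ordered collection of IOU thresholds `T_k` (0.50 to
#' 0.95 in steps of 0.05).  A predicted cell counts as a true positive at
#' `T_k` when its IOU with the assigned ground-truth cell strictly exceeds
#' `T_k`.  `iou_assign_threshold` is the single threshold used for the
#' per-cell average-IOU statistic: every ground-truth cell is assigned its
#' matched IOU when that exceeds the threshold, else 0.0 (false negative).
#'
#' @param thresholds strictly increasing IOU thresholds in `(0, 1)`.
#' @param iou_assign_threshold threshold for the average-IOU assignment.
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(thresholds = seq(0.5, 0.95, by = 0.05),
                        iou_assign_threshold = 0.5) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds < 1),
            iou_assign_threshold >= 0, iou_assign_threshold <= 1)
  structure(list(thresholds = thresholds,
                 iou_assign_threshold = iou_assign_threshold),
            class = "eval_config")
}

#' Pairwise IOU matrix between instance masks
#'
#' Entry `(i, j)` is the intersection-over-union of ground-truth cell `i`
#' and predicted cell `j`; 0 for disjoint cells.
#'
#' @param gt,pred integer instance label matrices of identical shape.
#' @return numeric matrix of size `n_gt x n_pred`.
#' @export
iou_matrix <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("instance masks differ in shape")
  n_gt <- max(gt, 0L); n_pred <- max(pred, 0L)
  if (n_gt == 0L || n_pred == 0L) return(matrix(0, n_gt, n_pred))
  both <- gt > 0L & pred > 0L
  inter <- matrix(0, n_gt, n_pred)
  if (any(both)) {
    tab <- table(factor(gt[both], levels = seq_len(n_gt)),
                 factor(pred[both], levels = seq_len(n_pred)))
    inter <- matrix(as.numeric(tab), n_gt, n_pred)
  }
  a_gt <- tabulate(gt[gt > 0L], nbins = n_gt)
  a_pred <- tabulate(pred[pred > 0L], nbins = n_pred)
  uni <- outer(a_gt, a_pred, `+`) - inter
  inter / uni
}

# Greedy one-to-one assignment on descending IOU with ties broken by lower
# predicted then lower ground-truth label id; only pairs with IOU > thr are
# assigned.  Returns an integer vector: for each gt cell the matched pred
# label or 0.
.greedy_match <- function(M, thr) {
  n_gt <- nrow(M); n_pred <- ncol(M)
  assign_gt <- integer(n_gt)
  if (n_gt == 0L || n_pred == 0L) return(assign_gt)
  cand <- which(M > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(assign_gt)
  iou <- M[cand]
  ord <- order(-iou, cand[, 2L], cand[, 1L])
  used_pred <- logical(n_pred)
  for (i in ord) {
    g <- cand[i, 1L]; p <- cand[i, 2L]
    if (assign_gt[g] == 0L && !used_pred[p]) {
      assign_gt[g] <- p
      used_pred[p] <- TRUE
    }
  }
  assign_gt
}

#' Match predicted cells to ground-truth cells
#'
#' For every threshold `T_k` a one-to-one assignment is computed (greedy on
#' descending IOU): ground-truth cells with a matched prediction of IOU
#' strictly greater than `T_k` count as true positives, unmatched
#' ground-truth cells as false negatives, and predictions matched to no
#' ground-truth cell as false positives.  Additionally each ground-truth
#' cell is assigned one value for the average-IOU statistic: its matched
#' IOU when that exceeds `iou_assign_threshold`, else 0.0.
#'
#' @param gt,pred integer instance label matrices of identical shape.
#' @param config an [eval_config()].
#' @return an object of class `match_result`: list with `per_gt_iou`
#'   (numeric vector, one entry per ground-truth cell) and `counts`
#'   (data.frame with columns `threshold`, `tp`, `fn`, `fp`).
#' @export
match_cells <- function(gt, pred, config = eval_config()) {
  M <- iou_matrix(gt, pred)
  n_gt <- nrow(M); n_pred <- ncol(M)
  amain <- .greedy_match(M, config$iou_assign_threshold)
  per_gt_iou <- numeric(n_gt)
  hit <- amain > 0L
  if (any(hit)) per_gt_iou[hit] <- M[cbind(which(hit), amain[hit])]
  counts <- do.call(rbind, lapply(config$thresholds, function(tk) {
    a <- .greedy_match(M, tk)
    tp <- sum(a > 0L)
    data.frame(threshold = tk, tp = tp, fn = n_gt - tp, fp = n_pred - tp)
  }))
  structure(list(per_gt_iou = per_gt_iou, counts = counts),
            class = "match_result")
}

#' AP50:95-style precision of one image
#'
#' `precision = (1/|{T_k}|) * sum_k TP_k / (TP_k + FN_k + FP_k)`.  An image
#' with neither ground-truth nor predicted cells scores 1 at every
#' threshold (vacuous truth).
#'
#' @param match a `match_result` from [match_cells()].
#' @return scalar precision in `[0, 1]`.
#' @export
precision <- function(match) {
  stopifnot(inherits(match, "match_result"))
  with(match$counts, {
    denom <- tp + fn + fp
    mean(ifelse(denom == 0L, 1, tp / denom))
  })
}

#' Evaluate a set of image pairs
#'
#' Computes, per image, the average assigned IOU over ground-truth cells and
#' the [precision()], then aggregates: mean and (population) standard
#' deviation of the per-image average IOUs, and the mean per-image
#' precision -- the `m +/- s` and percentage formats commonly reported.
#'
#' @param pairs non-empty list of `list(gt = ..., pred = ...)` instance-mask
#'   pairs.
#' @param config an [eval_config()].
#' @return list with `per_image` (data.frame), `mean_iou`, `sd_iou`,
#'   `mean_precision`.
#' @export
evaluate_dataset <- function(pairs, config = eval_config()) {
  if (length(pairs) == 0L) stop("empty evaluation set")
  rows <- lapply(seq_along(pairs), function(i) {
    m <- match_cells(pairs[[i]]$gt, pairs[[i]]$pred, config)
    n_gt <- length(m$per_gt_iou)
    n_pred <- max(pairs[[i]]$pred, 0L)
    avg_iou <- if (n_gt > 0L) mean(m$per_gt_iou)
    else if (n_pred == 0L) 1 else 0
    data.frame(image = i, n_gt = n_gt, n_pred = n_pred,
               avg_iou = avg_iou, precision = precision(m))
  })
  per_image <- do.call(rbind, rows)
  mu <- mean(per_image$avg_iou)
  list(per_image = per_image,
       mean_iou = mu,
       sd_iou = sqrt(mean((per_image$avg_iou - mu)^2)),
       mean_precision = mean(per_image$precision))
}
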