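# Evaluation: IoU, precision/recall, average precision at a fixed IoU
# threshold for boxes and masks, mAP50, paired t-tests, and parameter
# accounting.

#' Intersection over union of two instance masks
#'
#' @param a,b logical (or 0/1) matrices of identical shape.
#' @return `|A & B| / |A | B|`; raises an error when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share one raster shape")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) stop("IoU undefined: both masks are empty")
  sum(a & b) / u
}

#' Precision and recall from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`; each is defined as 0 when
#' its denominator is 0.
#'
#' @param counts list or vector with elements `TP`, `FP`, `FN`.
#' @return named numeric vector `c(precision=, recall=)`.
#' @export
precision_recall <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# Greedy one-to-one matching of predictions (descending score) to ground
# truth: each prediction takes the unmatched GT of highest IoU if that IoU
# reaches the threshold. Returns a logical TP flag per prediction, in the
# order of decreasing score.
match_predictions <- function(pred_scores, iou_matrix, iou_thr) {
  n <- length(pred_scores)
  tp <- logical(n)
  if (n == 0L) return(tp)
  ngt <- if (is.null(dim(iou_matrix))) 0L else ncol(iou_matrix)
  taken <- logical(ngt)
  ord <- order(-pred_scores)
  for (i in ord) {
    if (ngt == 0L) break
    ious <- iou_matrix[i, ]
    ious[taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[i] <- TRUE
      taken[j] <- TRUE
    }
  }
  tp
}

# area under the monotone (all-point interpolated) precision envelope
pr_curve_area <- function(tp_sorted, n_gt) {
  if (n_gt == 0L) stop("AP undefined without ground truth")
  if (length(tp_sorted) == 0L) return(0)
  ctp <- cumsum(tp_sorted)
  cfp <- cumsum(!tp_sorted)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}

#' Average precision at a fixed IoU threshold
#'
#' Predictions are matched greedily by descending score, one-to-one, to the
#' ground truth of the same image; a match requires IoU at or above
#' `iou_thr`. AP is the area under the monotone-interpolated
#' precision-recall curve.
#'
#' @param predictions data frame with `image_id`, `score`, and either box
#'   columns `x1, y1, x2, y2` (mode `"box"`) or a `mask` list column of
#'   logical matrices (mode `"mask"`).
#' @param ground_truth data frame with `image_id` and the same geometry
#'   columns (no score).
#' @param iou_thr match threshold, default 0.5.
#' @param mode `"box"` or `"mask"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(predictions, ground_truth, iou_thr = 0.5,
                              mode = c("box", "mask")) {
  mode <- match.arg(mode)
  n_gt <- nrow(ground_truth)
  if (n_gt == 0L) stop("AP undefined without ground truth")
  if (is.null(predictions) || nrow(predictions) == 0L) return(0)
  tp_all <- logical(0)
  score_all <- numeric(0)
  for (img in unique(c(predictions$image_id, ground_truth$image_id))) {
    p <- predictions[predictions$image_id == img, , drop = FALSE]
    g <- ground_truth[ground_truth$image_id == img, , drop = FALSE]
    if (nrow(p) == 0L) next
    iou <- matrix(0, nrow(p), nrow(g))
    if (nrow(g) > 0L)
      for (i in seq_len(nrow(p)))
        for (j in seq_len(nrow(g)))
          iou[i, j] <- if (mode == "box")
            box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                    as.numeric(g[j, c("x1", "y1", "x2", "y2")]))
          else mask_iou(p$mask[[i]], g$mask[[j]])
    tp <- match_predictions(p$score, iou, iou_thr)
    tp_all <- c(tp_all, tp)
    score_all <- c(score_all, p$score)
  }
  ord <- order(-score_all)
  pr_curve_area(tp_all[ord], n_gt)
}

#' Mean average precision over classes
#'
#' @param per_class_ap numeric vector of per-class APs (classes without
#'   ground truth excluded by the caller).
#' @return arithmetic mean.
#' @export
map50 <- function(per_class_ap) {
  if (length(per_class_ap) < 1L) stop("need at least one class with defined AP")
  mean(per_class_ap)
}

#' Paired t-test on repeated metric values
#'
#' Two-sided paired Student t-test on differences `x - y`; a zero-variance
#' nonzero difference yields `t = +/-Inf`, `p = 0`.
#'
#' @param x,y numeric vectors of equal length (>= 2), paired runs.
#' @return named vector `c(t=, p=)`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(c(t = 0, p = 1))
    return(c(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Count trainable parameters of a built model or layer
#'
#' Walks the layer tree and sums the lengths of every trainable array
#' (convolution kernels, biases, batch-norm scales/shifts, fusion weights).
#' Fixed buffers (running statistics, distribution-focal bin positions) are
#' excluded.
#'
#' @param model an `akb_model` or `akb_layer`.
#' @param unit `"count"` or `"K"` (thousands, as complexity tables report).
#' @return numeric scalar.
#' @export
count_parameters <- function(model, unit = c("count", "K")) {
  unit <- match.arg(unit)
  root <- if (inherits(model, "akb_model")) model$root else model
  n <- sum(vapply(nn_collect_params(root), function(p) length(p$val), numeric(1)))
  if (unit == "K") n / 1000 else n
}
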