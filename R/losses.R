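# Training objective terms: classification cross-entropy, squared-error box
# regression, and binary cross-entropy segmentation, combined as a weighted
# sum. These operate on plain numeric batches; the training loop applies the
# same functional forms through the autograd graph.

.clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Assemble a loss batch
#'
#' @param cls_target `N x C` one-hot class matrix (optional).
#' @param cls_pred `N x C` predicted class probabilities in (0, 1).
#' @param box_target,box_pred `N x 4` matrices of (x, y, w, h) in normalized
#'   image units (optional).
#' @param seg_target binary pixel labels (vector or array; optional).
#' @param seg_pred predicted pixel probabilities, same shape.
#' @param lambda_cor positive coordinate-loss weight.
#' @param weights length-3 non-negative term weights (cls, box, seg).
#' @return a list of class `loss_batch`.
#' @export
loss_batch <- function(cls_target = NULL, cls_pred = NULL,
                       box_target = NULL, box_pred = NULL,
                       seg_target = NULL, seg_pred = NULL,
                       lambda_cor = 1, weights = c(1, 1, 1)) {
  stopifnot(lambda_cor > 0, length(weights) == 3, all(weights >= 0))
  structure(list(cls_target = cls_target, cls_pred = cls_pred,
                 box_target = box_target, box_pred = box_pred,
                 seg_target = seg_target, seg_pred = seg_pred,
                 lambda_cor = lambda_cor, weights = weights),
            class = "loss_batch")
}

#' Classification cross-entropy over one-hot targets
#'
#' `-(1/N) * sum_i sum_c y_ic * log(p_ic)`, with probabilities clipped to
#' `(eps, 1 - eps)` before the log.
#'
#' @param batch a [loss_batch()].
#' @return non-negative scalar.
#' @export
classification_loss <- function(batch) {
  y <- batch$cls_target
  p <- .clip_prob(batch$cls_pred)
  if (!all(y %in% c(0, 1))) stop("class targets must be one-hot (0/1)")
  -sum(y * log(p)) / nrow(as.matrix(y))
}

#' Bounding-box regression loss
#'
#' The canonical form is the squared coordinate error
#' `lambda_cor * sum_i [(x-x^)^2 + (y-y^)^2 + (w-w^)^2 + (h-h^)^2]` over
#' matched prediction/target pairs in normalized (x, y, w, h) units;
#' `form = "ciou"` selects complete-IoU loss (`1 - IoU + center-distance
#' penalty + aspect-ratio penalty`, summed over pairs) as an alternative.
#'
#' @param batch a [loss_batch()].
#' @param form `"sq_error"` (default) or `"ciou"`.
#' @return non-negative scalar.
#' @export
box_loss <- function(batch, form = c("sq_error", "ciou")) {
  form <- match.arg(form)
  t <- as.matrix(batch$box_target); p <- as.matrix(batch$box_pred)
  if (form == "sq_error") {
    d <- t - p
    return(batch$lambda_cor * sum(d * d))
  }
  total <- 0
  for (i in seq_len(nrow(t))) {
    a <- c(t[i, 1] - t[i, 3] / 2, t[i, 2] - t[i, 4] / 2,
           t[i, 1] + t[i, 3] / 2, t[i, 2] + t[i, 4] / 2)
    b <- c(p[i, 1] - p[i, 3] / 2, p[i, 2] - p[i, 4] / 2,
           p[i, 1] + p[i, 3] / 2, p[i, 2] + p[i, 4] / 2)
    iou <- if (all(a[3:4] > a[1:2]) && all(b[3:4] > b[1:2])) box_iou(a, b) else 0
    cw <- max(a[3], b[3]) - min(a[1], b[1])
    ch <- max(a[4], b[4]) - min(a[2], b[2])
    rho2 <- (t[i, 1] - p[i, 1])^2 + (t[i, 2] - p[i, 2])^2
    c2 <- cw^2 + ch^2 + 1e-9
    v <- (4 / pi^2) * (atan(t[i, 3] / max(t[i, 4], 1e-9)) -
                         atan(p[i, 3] / max(p[i, 4], 1e-9)))^2
    alpha <- if (iou >= 0.5) v / (1 - iou + v + 1e-9) else 0
    total <- total + (1 - iou + rho2 / c2 + alpha * v)
  }
  total
}

#' Binary cross-entropy segmentation loss
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`.
#'
#' @param batch a [loss_batch()].
#' @return non-negative scalar.
#' @export
segmentation_loss <- function(batch) {
  y <- as.numeric(batch$seg_target)
  p <- .clip_prob(as.numeric(batch$seg_pred))
  if (!all(y %in% c(0, 1))) stop("segmentation targets must be binary")
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Weighted total loss
#'
#' `w_cls * L_cls + w_box * L_box + w_seg * L_seg`; absent terms contribute 0.
#'
#' @param batch a [loss_batch()].
#' @return non-negative scalar.
#' @export
total_loss <- function(batch) {
  w <- batch$weights
  l <- 0
  if (!is.null(batch$cls_pred) && w[1] > 0) l <- l + w[1] * classification_loss(batch)
  if (!is.null(batch$box_pred) && w[2] > 0) l <- l + w[2] * box_loss(batch)
  if (!is.null(batch$seg_pred) && w[3] > 0) l <- l + w[3] * segmentation_loss(batch)
  l
}
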