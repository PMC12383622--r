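# Non-maximum suppression with Gaussian score decay.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `(x1, y1, x2, y2)` in continuous half-open pixel coordinates
#' with `x2 > x1` and `y2 > y1`.
#'
#' @param a,b numeric length-4 vectors.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box: x2 > x1 and y2 > y1 required")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# pairwise IoU of one box against a matrix of boxes (n x 4)
.iou_one_many <- function(a, m) {
  iw <- pmin(a[3], m[, 3]) - pmax(a[1], m[, 1])
  ih <- pmin(a[4], m[, 4]) - pmax(a[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area <- (m[, 3] - m[, 1]) * (m[, 4] - m[, 2])
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + area - inter)
}

#' Configuration for score-decay NMS
#'
#' @param Nt IoU threshold above which a neighbour's score is decayed.
#' @param sigma Gaussian decay scale; the decay factor is
#'   `exp(-IoU^2 / sigma)`.
#' @param score_min final-score floor; detections decayed below it are dropped.
#' @param method `"gaussian"` (score decay) or `"hard"` (classic suppression).
#' @return a list of class `nms_config`.
#' @export
nms_config <- function(Nt = 0.5, sigma = 0.5, score_min = 0.001,
                       method = c("gaussian", "hard")) {
  method <- match.arg(method)
  stopifnot(Nt >= 0, Nt <= 1, sigma > 0, score_min >= 0, score_min <= 1)
  structure(list(Nt = Nt, sigma = sigma, score_min = score_min,
                 method = method), class = "nms_config")
}

.det_order <- function(d) order(-d$score, d$x1, d$y1, d$x2, d$y2)

#' Soft non-maximum suppression with Gaussian decay
#'
#' Iteratively moves the highest-scoring box to the keep set; every remaining
#' box whose IoU with it reaches `Nt` has its score multiplied by
#' `exp(-IoU^2 / sigma)`, boxes below `Nt` keep their score. Detections whose
#' final score falls below `score_min` are dropped. Ties are broken by score,
#' then lexicographically on box coordinates, so the result is independent of
#' input order.
#'
#' @param dets data frame with columns `x1, y1, x2, y2, score` (all one
#'   class; callers partition by class) and any extra columns to carry along.
#' @param cfg an [nms_config()].
#' @return the kept detections, scores decayed, sorted by decayed score.
#' @export
soft_nms <- function(dets, cfg = nms_config()) {
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  if (cfg$method == "hard") return(hard_nms(dets, cfg$Nt))
  work <- dets
  keep <- integer(0)
  kept_scores <- numeric(0)
  idx <- seq_len(nrow(work))
  score <- work$score
  alive <- rep(TRUE, nrow(work))
  while (any(alive)) {
    cand <- which(alive)
    o <- cand[.det_order(data.frame(score = score[cand], work[cand, c("x1", "y1", "x2", "y2")]))][1]
    keep <- c(keep, o)
    kept_scores <- c(kept_scores, score[o])
    alive[o] <- FALSE
    rest <- which(alive)
    if (length(rest) > 0L) {
      iou <- .iou_one_many(as.numeric(work[o, c("x1", "y1", "x2", "y2")]),
                           as.matrix(work[rest, c("x1", "y1", "x2", "y2")]))
      decay <- ifelse(iou >= cfg$Nt, exp(-iou^2 / cfg$sigma), 1)
      score[rest] <- score[rest] * decay
    }
  }
  out <- work[keep, , drop = FALSE]
  out$score <- kept_scores
  out <- out[out$score >= cfg$score_min, , drop = FALSE]
  out <- out[.det_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classic greedy non-maximum suppression
#'
#' Keeps the highest-scoring box and removes every remaining box whose IoU
#' with it exceeds `iou_thr`; repeats until no boxes remain. Equals
#' [soft_nms()] in the `sigma -> 0` limit followed by any positive score
#' floor.
#'
#' @inheritParams soft_nms
#' @param iou_thr suppression threshold.
#' @export
hard_nms <- function(dets, iou_thr = 0.5) {
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  work <- dets
  keep <- integer(0)
  alive <- rep(TRUE, nrow(work))
  while (any(alive)) {
    cand <- which(alive)
    o <- cand[.det_order(work[cand, , drop = FALSE])][1]
    keep <- c(keep, o)
    alive[o] <- FALSE
    rest <- which(alive)
    if (length(rest) > 0L) {
      iou <- .iou_one_many(as.numeric(work[o, c("x1", "y1", "x2", "y2")]),
                           as.matrix(work[rest, c("x1", "y1", "x2", "y2")]))
      alive[rest[iou > iou_thr]] <- FALSE
    }
  }
  out <- work[keep, , drop = FALSE]
  out <- out[.det_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
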