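# Independent reference implementations used as oracles. These are written
# as direct transcriptions of the definitions (loops, enumeration), kept
# deliberately separate from the package's vectorized/compiled paths.

# plain histogram equalization by direct CDF mapping (256 bins)
oracle_histeq <- function(img) {
  q <- as.integer(round(img * 255))
  h <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(h)
  n <- length(q)
  cdfmin <- min(cdf[cdf > 0])
  if (n == cdfmin) return(img)
  map <- as.integer(round(pmax(cdf - cdfmin, 0) / (n - cdfmin) * 255))
  out <- map[q + 1L] / 255
  dim(out) <- dim(img)
  out
}

# greedy hard NMS by explicit O(n^2) pairwise loops
oracle_hard_nms <- function(dets, thr) {
  n <- nrow(dets)
  ord <- order(-dets$score, dets$x1, dets$y1, dets$x2, dets$y2)
  suppressed <- rep(FALSE, n)
  keep <- integer(0)
  for (ii in seq_len(n)) {
    i <- ord[ii]
    if (suppressed[i]) next
    keep <- c(keep, i)
    for (jj in seq_len(n)) {
      j <- ord[jj]
      if (j == i || suppressed[j]) next
      if (akbseg::box_iou(as.numeric(dets[i, 1:4]), as.numeric(dets[j, 1:4])) > thr)
        suppressed[j] <- TRUE
    }
  }
  sort(keep)
}

# Gaussian score-decay suppression transcribed literally from the piecewise
# rule: decay neighbours with IoU >= Nt by exp(-IoU^2/sigma), keep the rest
oracle_soft_nms <- function(dets, Nt, sigma, score_min) {
  boxes <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  s <- dets$score
  remaining <- seq_len(nrow(dets))
  kept <- integer(0)
  kept_s <- numeric(0)
  while (length(remaining) > 0) {
    rs <- s[remaining]
    o <- order(-rs, boxes[remaining, 1], boxes[remaining, 2],
               boxes[remaining, 3], boxes[remaining, 4])[1]
    m <- remaining[o]
    kept <- c(kept, m)
    kept_s <- c(kept_s, s[m])
    remaining <- setdiff(remaining, m)
    for (i in remaining) {
      iou <- akbseg::box_iou(boxes[m, ], boxes[i, ])
      if (iou >= Nt) s[i] <- s[i] * exp(-iou^2 / sigma)
    }
  }
  ok <- kept_s >= score_min
  data.frame(idx = kept[ok], score = kept_s[ok])
}

# average precision by exhaustive score-cutoff sweep with fresh greedy
# matching at every cutoff, then the area under the monotone envelope
oracle_ap_sweep <- function(preds, gts, iou_thr) {
  n_gt <- nrow(gts)
  match_at <- function(cut) {
    tp <- 0L; fp <- 0L
    for (img in unique(preds$image_id)) {
      p <- preds[preds$image_id == img & preds$score >= cut, , drop = FALSE]
      g <- gts[gts$image_id == img, , drop = FALSE]
      if (nrow(p) == 0) next
      p <- p[order(-p$score), , drop = FALSE]
      used <- rep(FALSE, nrow(g))
      for (i in seq_len(nrow(p))) {
        best <- 0; bj <- 0
        for (j in seq_len(nrow(g))) {
          if (used[j]) next
          iou <- akbseg::box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                                 as.numeric(g[j, c("x1", "y1", "x2", "y2")]))
          if (iou > best) { best <- iou; bj <- j }
        }
        if (bj > 0 && best >= iou_thr) { tp <- tp + 1L; used[bj] <- TRUE }
        else fp <- fp + 1L
      }
    }
    c(tp = tp, fp = fp)
  }
  cuts <- sort(unique(preds$score), decreasing = TRUE)
  rec <- numeric(0); prec <- numeric(0)
  for (cut in cuts) {
    m <- match_at(cut)
    rec <- c(rec, m["tp"] / n_gt)
    prec <- c(prec, if (sum(m) > 0) m["tp"] / sum(m) else 0)
  }
  ord <- order(rec)
  rec <- rec[ord]; prec <- prec[ord]
  penv <- rev(cummax(rev(prec)))
  sum((rec - c(0, rec[-length(rec)])) * penv)
}

# random detection set on a small canvas
random_dets <- function(n, size = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- runif(n, 0, size - 6); y1 <- runif(n, 0, size - 6)
  w <- runif(n, 3, 14); h <- runif(n, 3, 14)
  data.frame(x1 = x1, y1 = y1, x2 = pmin(x1 + w, size), y2 = pmin(y1 + h, size),
             score = round(runif(n, 0.05, 0.999), 3))
}
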