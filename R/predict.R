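# Inference: decoding head outputs to detections, Soft-NMS, prototype-mask
# assembly, and mapping results back to the original image frame.

.softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# decode one level's raw head maps (values, batch size 1) to detections
.decode_level <- function(box_arr, cls_arr, coef_arr, stride, conf) {
  G1 <- dim(cls_arr)[1]; G2 <- dim(cls_arr)[2]
  nc <- dim(cls_arr)[3]
  nb <- dim(box_arr)[3] %/% 4L
  dets <- NULL
  for (cl in seq_len(nc)) {
    sc <- 1 / (1 + exp(-cls_arr[, , cl, 1]))
    hits <- which(sc >= conf, arr.ind = TRUE)
    if (is.null(dim(hits))) hits <- matrix(hits, ncol = 2)
    if (nrow(hits) == 0L) next
    logits <- matrix(0, nrow(hits), 4L * nb)
    for (c in seq_len(4L * nb))
      logits[, c] <- box_arr[cbind(hits[, 1], hits[, 2], c, 1L)]
    ks <- seq_len(nb) - 1
    dist <- sapply(1:4, function(s)
      .softmax_rows(logits[, (s - 1) * nb + seq_len(nb), drop = FALSE]) %*% ks)
    dist <- matrix(dist, nrow(hits), 4)
    cx <- (hits[, 2] - 0.5) * stride
    cy <- (hits[, 1] - 0.5) * stride
    d <- data.frame(
      x1 = cx - dist[, 1] * stride, y1 = cy - dist[, 2] * stride,
      x2 = cx + dist[, 3] * stride, y2 = cy + dist[, 4] * stride,
      score = sc[hits], class_id = cl - 1L)
    nm <- dim(coef_arr)[3]
    cf <- matrix(0, nrow(hits), nm)
    for (c in seq_len(nm)) cf[, c] <- coef_arr[cbind(hits[, 1], hits[, 2], c, 1L)]
    d$coef <- I(lapply(seq_len(nrow(cf)), function(i) cf[i, ]))
    dets <- rbind(dets, d)
  }
  dets
}

#' Segment an image
#'
#' Letterboxes the image to the network input, runs the forward pass in
#' evaluation mode, decodes candidate boxes, applies per-class NMS
#' (Gaussian Soft-NMS for the Soft-NMS variants, classic suppression for the
#' baseline, or as overridden by `nms`), assembles prototype masks for the
#' surviving detections (binarized at `mask_threshold`), and maps boxes and
#' masks back to the original frame.
#'
#' @param model trained `akb_model`.
#' @param image grayscale matrix or RGB array in `[0,1]`.
#' @param nms an [nms_config()]; default follows the model variant.
#' @param conf minimum pre-NMS candidate score.
#' @param max_det detection cap after NMS.
#' @param mask_threshold binarization threshold of assembled masks.
#' @param image_id identifier carried into the result.
#' @return list of class `segmentation_result`: `detections` (data frame
#'   `x1, y1, x2, y2, score, class_id` in original pixel coords), `masks`
#'   (list of logical matrices at the original size, one per detection),
#'   `image_id`.
#' @export
predict_image <- function(model, image, nms = NULL, conf = 0.25,
                          max_det = 300L, mask_threshold = 0.5,
                          image_id = NA) {
  spec <- model$spec
  if (is.null(nms))
    nms <- nms_config(method = if (spec$use_softnms) "gaussian" else "hard")
  S <- spec$input_size
  g <- as_gray(image)
  H0 <- nrow(g); W0 <- ncol(g)
  lb <- letterbox(g, S)
  x <- array(lb$image, c(S, S, 3, 1))
  out <- model_forward(model, x, training = FALSE)
  dets <- NULL
  for (l in 1:3) {
    dl <- .decode_level(out$levels[[l]]$box$val, out$levels[[l]]$cls$val,
                        out$levels[[l]]$coef$val, spec$strides[l], conf)
    dets <- rbind(dets, dl)
  }
  empty <- list(detections = data.frame(x1 = numeric(0), y1 = numeric(0),
                                        x2 = numeric(0), y2 = numeric(0),
                                        score = numeric(0), class_id = integer(0)),
                masks = list(), image_id = image_id)
  class(empty) <- "segmentation_result"
  if (is.null(dets) || nrow(dets) == 0L) return(empty)
  # clamp candidate boxes to the letterboxed frame, drop degenerates
  dets$x1 <- pmax(dets$x1, 0); dets$y1 <- pmax(dets$y1, 0)
  dets$x2 <- pmin(dets$x2, S); dets$y2 <- pmin(dets$y2, S)
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  if (nrow(dets) == 0L) return(empty)
  kept <- NULL
  for (cl in unique(dets$class_id)) {
    part <- dets[dets$class_id == cl, , drop = FALSE]
    part <- if (nms$method == "gaussian") soft_nms(part, nms)
            else hard_nms(part, nms$Nt)
    kept <- rbind(kept, part)
  }
  kept <- kept[order(-kept$score), , drop = FALSE]
  if (nrow(kept) > max_det) kept <- kept[seq_len(max_det), , drop = FALSE]
  # prototype masks at stride 4, cropped to the detection box
  proto <- out$proto$val
  gp <- dim(proto)[1]
  pm <- matrix(proto, gp * gp)
  masks <- vector("list", nrow(kept))
  ok <- rep(TRUE, nrow(kept))
  for (i in seq_len(nrow(kept))) {
    logit <- matrix(pm %*% kept$coef[[i]], gp, gp)
    mk <- 1 / (1 + exp(-logit)) >= mask_threshold
    # crop to box (proto-grid coords)
    rows <- max(1, floor(kept$y1[i] / 4)):min(gp, ceiling(kept$y2[i] / 4))
    cols <- max(1, floor(kept$x1[i] / 4)):min(gp, ceiling(kept$x2[i] / 4))
    crop <- matrix(FALSE, gp, gp)
    crop[rows, cols] <- mk[rows, cols]
    # back-map to original pixels (nearest sampling through the letterbox)
    oy <- round(((seq_len(H0) - 0.5) * lb$scale + lb$dy) / 4 + 0.5)
    ox <- round(((seq_len(W0) - 0.5) * lb$scale + lb$dx) / 4 + 0.5)
    oy <- pmin(pmax(oy, 1), gp); ox <- pmin(pmax(ox, 1), gp)
    masks[[i]] <- crop[oy, ox, drop = FALSE]
    if (!any(masks[[i]])) ok[i] <- FALSE
  }
  kept$coef <- NULL
  # boxes back to the original frame
  kept$x1 <- pmin(pmax((kept$x1 - lb$dx) / lb$scale, 0), W0)
  kept$x2 <- pmin(pmax((kept$x2 - lb$dx) / lb$scale, 0), W0)
  kept$y1 <- pmin(pmax((kept$y1 - lb$dy) / lb$scale, 0), H0)
  kept$y2 <- pmin(pmax((kept$y2 - lb$dy) / lb$scale, 0), H0)
  keep2 <- ok & kept$x2 > kept$x1 & kept$y2 > kept$y1
  kept <- kept[keep2, , drop = FALSE]
  masks <- masks[keep2]
  rownames(kept) <- NULL
  res <- list(detections = kept, masks = masks, image_id = image_id)
  class(res) <- "segmentation_result"
  res
}

# parse a COCO-style annotation JSON into evaluation tables (masks
# rasterized from polygon segmentations; a "score" field is honoured)
.coco_to_eval <- function(path) {
  cc <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- list()
  for (im in cc$images) dims[[as.character(im$id)]] <- c(im$height, im$width)
  rows <- NULL; masks <- list()
  for (a in cc$annotations) {
    d <- dims[[as.character(a$image_id)]]
    v <- as.numeric(unlist(a$segmentation[[1]]))
    poly <- cbind(v[seq(1, length(v), 2)], v[seq(2, length(v), 2)])
    m <- polygon_to_mask(poly, d[1], d[2])
    if (!any(m)) next
    w <- which(m, arr.ind = TRUE)
    rows <- rbind(rows, data.frame(
      image_id = a$image_id,
      x1 = min(w[, 2]) - 1, y1 = min(w[, 1]) - 1,
      x2 = max(w[, 2]), y2 = max(w[, 1]),
      score = if (is.null(a$score)) 1 else a$score))
    masks[[length(masks) + 1L]] <- m
  }
  if (!is.null(rows)) rows$mask <- I(masks)
  rows
}

#' Evaluate COCO-style predictions against ground truth
#'
#' Both files are COCO-style annotation JSONs with polygon segmentations;
#' prediction annotations may carry a `score` field (missing scores count
#' as 1). Reports box and mask AP at the IoU threshold plus
#' precision/recall of the score-ranked matching.
#'
#' @param pred_json,gt_json file paths.
#' @param iou_thr match threshold.
#' @return list with `map50_box`, `map50_mask`, `precision`, `recall`.
#' @export
evaluate_coco <- function(pred_json, gt_json, iou_thr = 0.5) {
  preds <- .coco_to_eval(pred_json)
  gts <- .coco_to_eval(gt_json)
  if (is.null(gts)) stop("no ground-truth annotations")
  if (is.null(preds))
    return(list(map50_box = 0, map50_mask = 0, precision = 0, recall = 0))
  gts$score <- NULL
  ap_box <- average_precision(preds, gts, iou_thr, "box")
  ap_mask <- average_precision(preds, gts, iou_thr, "mask")
  tp <- 0L
  for (img in unique(gts$image_id)) {
    p <- preds[preds$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    if (nrow(p) == 0L) next
    iou <- outer(seq_len(nrow(p)), seq_len(nrow(g)), Vectorize(function(i, j)
      box_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
              as.numeric(g[j, c("x1", "y1", "x2", "y2")]))))
    tp <- tp + sum(match_predictions(p$score, matrix(iou, nrow(p)), iou_thr))
  }
  pr <- precision_recall(c(TP = tp, FP = nrow(preds) - tp, FN = nrow(gts) - tp))
  list(map50_box = ap_box, map50_mask = ap_mask,
       precision = unname(pr["precision"]), recall = unname(pr["recall"]))
}

#' Evaluate a model on scenes with ground truth
#'
#' Runs [predict_image()] on every scene, pools predictions and ground
#' truth, and computes single-class AP at the IoU threshold for boxes and
#' masks.
#'
#' @param model trained `akb_model`.
#' @param scenes list of scenes with `image`, `boxes`, `instances`.
#' @param conf pre-NMS score threshold (low for AP evaluation).
#' @param iou_thr match threshold.
#' @param nms optional [nms_config()] override.
#' @return list: `map50_box`, `map50_mask`, `predictions`, `ground_truth`.
#' @export
evaluate_model <- function(model, scenes, conf = 0.05, iou_thr = 0.5,
                           nms = NULL) {
  preds <- NULL; gts <- NULL
  pred_masks <- list(); gt_masks <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    r <- predict_image(model, sc$image, nms = nms, conf = conf, image_id = i)
    if (nrow(r$detections) > 0) {
      d <- r$detections
      d$image_id <- i
      preds <- rbind(preds, d)
      pred_masks <- c(pred_masks, r$masks)
    }
    if (nrow(sc$boxes) > 0) {
      g <- as.data.frame(sc$boxes)
      g$image_id <- i
      gts <- rbind(gts, g)
      gt_masks <- c(gt_masks, sc$instances)
    }
  }
  if (is.null(gts)) stop("no ground truth in scenes")
  if (is.null(preds))
    return(list(map50_box = 0, map50_mask = 0, predictions = NULL,
                ground_truth = gts))
  preds$mask <- I(pred_masks)
  gts$mask <- I(gt_masks)
  ap_box <- average_precision(preds, gts, iou_thr, mode = "box")
  ap_mask <- average_precision(preds, gts, iou_thr, mode = "mask")
  list(map50_box = map50(ap_box), map50_mask = map50(ap_mask),
       predictions = preds, ground_truth = gts)
}
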