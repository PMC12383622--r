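# Training: letterboxing, target assignment, the loss graph, the SGD loop,
# and self-describing checkpoints.
#
# The objective follows the package's loss formulas: one-vs-all
# cross-entropy on the classification map, squared-error regression on the
# decoded (x, y, w, h) in normalized image units (weight lambda_cor), and
# binary cross-entropy on assembled prototype masks, summed with the
# configured term weights and normalized by the number of assigned
# positives.

#' Training configuration
#'
#' Defaults are the full-scale recipe (640 px, batch 16, 200 epochs, SGD
#' momentum 0.9, initial learning rate 0.001, weight decay 0.0005); desk
#' scale runs override them.
#'
#' @param epochs,batch_size,lr,momentum,weight_decay SGD settings.
#' @param input_size square network input (multiple of 32); images are
#'   letterboxed to it.
#' @param lambda_cls,lambda_box,lambda_seg term weights of the total loss.
#' @param lambda_cor coordinate-loss weight inside the box term.
#' @param lr_final_frac final learning rate as a fraction of `lr` (linear
#'   decay; 1 = constant).
#' @param seed RNG seed controlling shuffling (and any augmentation).
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 16L, lr = 0.001,
                         momentum = 0.9, weight_decay = 0.0005,
                         input_size = 640L, lambda_cls = 1, lambda_box = 5,
                         lambda_seg = 1, lambda_cor = 1,
                         lr_final_frac = 0.1, seed = 0L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0, momentum >= 0,
            momentum < 1, weight_decay >= 0, input_size %% 32 == 0)
  structure(as.list(environment()), class = "train_config")
}

# bilinear resize of a matrix
resize_bilinear <- function(m, nh, nw) {
  H <- nrow(m); W <- ncol(m)
  rr <- ( (seq_len(nh) - 0.5) * H / nh ) - 0.5
  cc <- ( (seq_len(nw) - 0.5) * W / nw ) - 0.5
  pts <- cbind(rep(rr, nw), rep(cc, each = nh))
  matrix(cpp_bilinear_at(m, pts), nh, nw)
}

#' Letterbox an image to a square network input
#'
#' Preserves aspect ratio, pads with neutral gray (114/255), and returns the
#' mapping needed to take predictions back to the original frame.
#'
#' @param img grayscale matrix or `H x W x 3` array in `[0,1]`.
#' @param size target square side.
#' @return list: `image` (`size x size x 3`), `scale`, `dx`, `dy` (pixel
#'   offsets of the valid region).
#' @export
letterbox <- function(img, size) {
  g <- as_gray(img)
  H <- nrow(g); W <- ncol(g)
  scale <- min(size / H, size / W)
  nh <- round(H * scale); nw <- round(W * scale)
  rs <- if (nh == H && nw == W) g else resize_bilinear(g, nh, nw)
  dy <- (size - nh) %/% 2L; dx <- (size - nw) %/% 2L
  canvas <- matrix(114 / 255, size, size)
  canvas[dy + seq_len(nh), dx + seq_len(nw)] <- rs
  out <- array(canvas, c(size, size, 1))[, , c(1, 1, 1), drop = FALSE]
  list(image = out, scale = scale, dx = dx, dy = dy)
}

# ground-truth mask -> prototype-resolution (size/4) letterboxed raster
.mask_to_proto <- function(mask, scale, dx, dy, psize) {
  ctr <- (seq_len(psize) - 0.5) * 4          # letterbox px of proto cell centers
  src_r <- round((rep(ctr, psize) - dy) / scale)
  src_c <- round((rep(ctr, each = psize) - dx) / scale)
  ok <- src_r >= 1 & src_r <= nrow(mask) & src_c >= 1 & src_c <= ncol(mask)
  v <- logical(psize * psize)
  v[ok] <- mask[cbind(src_r[ok], src_c[ok])]
  matrix(v, psize, psize)
}

# assign each ground-truth box to (level, cell); returns per-level positives
.assign_targets <- function(boxes_by_img, S, strides, batch_ids) {
  nl <- length(strides)
  grids <- S %/% strides
  pos <- lapply(seq_len(nl), function(l)
    list(cells = matrix(0L, 0, 3), xywh = matrix(0, 0, 4),
         img = integer(0), inst = integer(0)))
  taken <- lapply(seq_len(nl), function(l) new.env(parent = emptyenv()))
  inst_counter <- 0L
  for (k in seq_along(boxes_by_img)) {
    bx <- boxes_by_img[[k]]
    b <- batch_ids[k]
    for (j in seq_len(nrow(bx))) {
      inst_counter <- inst_counter + 1L
      w <- bx[j, 3] - bx[j, 1]; h <- bx[j, 4] - bx[j, 2]
      if (w <= 0 || h <= 0) next
      s <- sqrt(w * h)
      pref <- order(abs(log2(s / (4 * strides))))
      placed <- FALSE
      for (l in pref) {
        st <- strides[l]; G <- grids[l]
        gx <- min(max(floor((bx[j, 1] + w / 2) / st), 0), G - 1)
        gy <- min(max(floor((bx[j, 2] + h / 2) / st), 0), G - 1)
        key <- paste(b, gy, gx, sep = "_")
        if (!is.null(taken[[l]][[key]])) next
        taken[[l]][[key]] <- TRUE
        pos[[l]]$cells <- rbind(pos[[l]]$cells, c(gy + 1L, gx + 1L, b))
        pos[[l]]$xywh <- rbind(pos[[l]]$xywh,
                               c((bx[j, 1] + w / 2) / S, (bx[j, 2] + h / 2) / S,
                                 w / S, h / S))
        pos[[l]]$img <- c(pos[[l]]$img, b)
        pos[[l]]$inst <- c(pos[[l]]$inst, inst_counter)
        placed <- TRUE
        break
      }
      # crowded cell on every level: instance contributes no positive
    }
  }
  pos
}

# distances (l,t,r,b in stride units) -> normalized xywh, per level
.dist_to_xywh_mats <- function(cells, stride, S) {
  k <- stride / S
  T_mat <- matrix(0, 4, 4)
  T_mat[1, 1] <- -k / 2; T_mat[3, 1] <- k / 2   # x center
  T_mat[2, 2] <- -k / 2; T_mat[4, 2] <- k / 2   # y center
  T_mat[1, 3] <- k; T_mat[3, 3] <- k            # width
  T_mat[2, 4] <- k; T_mat[4, 4] <- k            # height
  C_mat <- cbind((cells[, 2] - 0.5) * stride / S,
                 (cells[, 1] - 0.5) * stride / S, 0, 0)
  list(T = T_mat, C = C_mat)
}

# build the loss graph for one prepared batch
.loss_graph <- function(model, xb, targets, cfg) {
  spec <- model$spec
  S <- cfg$input_size
  strides <- spec$strides
  out <- model_forward(model, xb, training = TRUE)
  npos <- max(1L, sum(vapply(targets$pos, function(p) nrow(p$cells), numeric(1))))
  # classification
  cls_nodes <- list()
  for (l in 1:3) {
    tgt <- targets$cls[[l]]
    cls_nodes[[l]] <- op_bce_logits(out$levels[[l]]$cls, tgt, reduction = "sum")
  }
  l_cls <- op_scale(op_sum_scalar(cls_nodes), cfg$lambda_cls / npos)
  # boxes: decode distribution-focal distances, squared error on xywh
  box_nodes <- list(); seg_coef <- list(); seg_img <- integer(0); seg_inst <- integer(0)
  for (l in 1:3) {
    p <- targets$pos[[l]]
    if (nrow(p$cells) == 0L) next
    gb <- op_gather_cells(out$levels[[l]]$box, p$cells)
    d <- op_dfl_decode(gb, spec$reg_max)
    mats <- .dist_to_xywh_mats(p$cells, strides[l], S)
    pred <- op_matconst(d, mats$T, mats$C)
    box_nodes[[length(box_nodes) + 1L]] <- op_sse(pred, p$xywh, scale = cfg$lambda_cor)
    seg_coef[[length(seg_coef) + 1L]] <- op_gather_cells(out$levels[[l]]$coef, p$cells)
    seg_img <- c(seg_img, p$img)
    seg_inst <- c(seg_inst, p$inst)
  }
  l_box <- if (length(box_nodes))
    op_scale(op_sum_scalar(box_nodes), cfg$lambda_box / npos)
  else ag_const(0)
  # masks: prototype assembly, BCE inside the padded ground-truth box
  if (length(seg_coef)) {
    coefs <- op_rowbind(seg_coef)
    asm <- op_mask_assemble(out$proto, coefs, seg_img)
    gp <- dim(out$proto$val)[1]
    n <- length(seg_inst)
    tmat <- matrix(0, gp * gp, n)
    wmat <- matrix(0, gp * gp, n)
    for (j in seq_len(n)) {
      pm <- targets$proto_masks[[seg_inst[j]]]
      tmat[, j] <- as.numeric(pm)
      win <- targets$proto_windows[[seg_inst[j]]]
      wv <- matrix(0, gp, gp)
      wv[win$rows, win$cols] <- 1
      wmat[, j] <- as.vector(wv) / max(1, sum(wv))
    }
    l_seg <- op_scale(op_bce_logits(asm, tmat, weight = wmat, reduction = "sum"),
                      cfg$lambda_seg / n)
  } else l_seg <- ag_const(0)
  total <- op_sum_scalar(list(l_cls, l_box, l_seg))
  list(total = total, cls = l_cls$val, box = l_box$val, seg = l_seg$val)
}

# prepare one scene for the trainer (letterbox + targets at input scale)
.prep_sample <- function(scene, S) {
  lb <- letterbox(scene$image, S)
  boxes <- scene$boxes
  if (nrow(boxes) > 0) {
    boxes <- cbind(boxes[, 1] * lb$scale + lb$dx, boxes[, 2] * lb$scale + lb$dy,
                   boxes[, 3] * lb$scale + lb$dx, boxes[, 4] * lb$scale + lb$dy)
  }
  gp <- S %/% 4L
  pmasks <- lapply(scene$instances, .mask_to_proto,
                   scale = lb$scale, dx = lb$dx, dy = lb$dy, psize = gp)
  pwin <- lapply(seq_along(pmasks), function(j) {
    b <- boxes[j, ] / 4
    w <- b[3] - b[1]; h <- b[4] - b[2]
    rows <- max(1, floor(b[2] - 0.2 * h)):min(gp, ceiling(b[4] + 0.2 * h))
    cols <- max(1, floor(b[1] - 0.2 * w)):min(gp, ceiling(b[3] + 0.2 * w))
    list(rows = rows, cols = cols)
  })
  list(x = lb$image, boxes = boxes, proto_masks = pmasks, proto_windows = pwin)
}

.batch_targets <- function(samples, spec, S) {
  B <- length(samples)
  grids <- S %/% spec$strides
  cls <- lapply(1:3, function(l) array(0, c(grids[l], grids[l], spec$num_classes, B)))
  pos <- .assign_targets(lapply(samples, `[[`, "boxes"), S, spec$strides, seq_len(B))
  for (l in 1:3) {
    p <- pos[[l]]
    if (nrow(p$cells) > 0)
      cls[[l]][cbind(p$cells[, 1], p$cells[, 2], 1L, p$cells[, 3])] <- 1
  }
  # flatten per-image instance lists in assignment order (instance counter
  # runs through images in batch order)
  proto_masks <- do.call(c, lapply(samples, `[[`, "proto_masks"))
  proto_windows <- do.call(c, lapply(samples, `[[`, "proto_windows"))
  list(cls = cls, pos = pos, proto_masks = proto_masks,
       proto_windows = proto_windows)
}

#' Train a segmentation model
#'
#' Full-batch SGD with momentum over letterboxed images. The loss combines
#' classification cross-entropy over all pyramid cells, squared-error
#' regression of decoded boxes, and prototype-mask binary cross-entropy,
#' normalized by the number of assigned positives.
#'
#' @param model an `akb_model` (modified in place).
#' @param data list of scenes (`synthetic_scene` or [read_dataset()] items),
#'   or a dataset directory path.
#' @param cfg a [train_config()]; `cfg$input_size` must match
#'   `model$spec$input_size`.
#' @param checkpoint_path optional path; the final state is saved there.
#' @return data frame with per-epoch `loss`, `cls`, `box`, `seg`.
#' @export
train_model <- function(model, data, cfg = train_config(),
                        checkpoint_path = NULL) {
  if (is.character(data)) data <- read_dataset(data)
  if (length(data) == 0L) stop("empty dataset")
  for (i in seq_along(data))
    if (is.null(data[[i]]$boxes) || is.null(data[[i]]$instances))
      stop(sprintf("malformed scene %d: boxes/instances missing", i))
  S <- cfg$input_size
  if (S != model$spec$input_size)
    stop("cfg$input_size must match model$spec$input_size")
  samples <- lapply(data, .prep_sample, S = S)
  if (is.null(model$state$rng)) set.seed(cfg$seed) else
    assign(".Random.seed", model$state$rng, envir = globalenv())
  nb <- ceiling(length(samples) / cfg$batch_size)
  hist <- data.frame()
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$lr * (1 - (1 - cfg$lr_final_frac) * (ep - 1) / max(1, cfg$epochs - 1))
    ord <- sample(length(samples))
    ep_loss <- c(total = 0, cls = 0, box = 0, seg = 0)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, length(samples))]
      batch <- samples[sel]
      xb <- array(0, c(S, S, 3, length(batch)))
      for (k in seq_along(batch)) xb[, , , k] <- batch[[k]]$x
      tg <- .batch_targets(batch, model$spec, S)
      ls <- .loss_graph(model, xb, tg, cfg)
      ag_zero_grad(model$params)
      ag_backward(ls$total)
      sgd_step(model$params, lr_ep, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + c(ls$total$val, ls$cls, ls$box, ls$seg)
    }
    ep_loss <- ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss[1],
                                   cls = ep_loss[2], box = ep_loss[3],
                                   seg = ep_loss[4]))
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.4f (cls %.4f box %.4f seg %.4f)",
                      ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
  }
  # refresh running statistics with the final weights (up to 10 batches)
  nref <- min(nb, 10L)
  xbatches <- lapply(seq_len(nref), function(bi) {
    sel <- ((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, length(samples))
    xb <- array(0, c(S, S, 3, length(sel)))
    for (k in seq_along(sel)) xb[, , , k] <- samples[[sel[k]]]$x
    xb
  })
  .refresh_bn_stats(model, xbatches)
  model$state$rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path, cfg)
  invisible(hist)
}

# Re-estimate batch-norm running statistics under the final weights: the
# exponential averages accumulated during training lag the weight updates,
# which degrades evaluation-mode behaviour (severely so for batch size 1).
# A plain running average over forward passes replaces them.
.refresh_bn_stats <- function(model, xbatches) {
  bn <- .bn_layers(model$root)
  for (l in bn) { l$running_mean[] <- 0; l$running_var[] <- 0 }
  for (i in seq_along(xbatches)) {
    for (l in bn) l$bn_momentum <- 1 / i
    model_forward(model, xbatches[[i]], training = TRUE)
  }
  for (l in bn) l$bn_momentum <- 0.1
  invisible(NULL)
}

# deterministic walk over layers carrying batch-norm state
.bn_layers <- function(layer, acc = list()) {
  if (!is.null(layer$running_mean)) acc[[length(acc) + 1L]] <- layer
  for (s in layer$sub) acc <- .bn_layers(s, acc)
  acc
}

#' Save a self-describing checkpoint
#'
#' Stores the spec, seed, all parameter values, batch-norm running
#' statistics, optimizer momenta, and the RNG state, so training can resume
#' exactly.
#'
#' @param model an `akb_model`.
#' @param path destination file.
#' @param cfg optional [train_config()] stored alongside.
#' @export
save_checkpoint <- function(model, path, cfg = NULL) {
  bn <- .bn_layers(model$root)
  state <- list(
    spec = model$spec, seed = model$seed, train_config = cfg,
    params = lapply(model$params, function(p) p$val),
    momenta = lapply(model$params, function(p) p$momentum),
    bn = lapply(bn, function(l) list(rm = l$running_mean, rv = l$running_var)),
    rng_state = model$state$rng)
  saveRDS(state, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return an `akb_model` with restored weights, statistics, and RNG state.
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_model(st$spec, seed = st$seed)
  for (i in seq_along(model$params)) {
    model$params[[i]]$val <- st$params[[i]]
    model$params[[i]]$momentum <- st$momenta[[i]]
  }
  bn <- .bn_layers(model$root)
  for (i in seq_along(bn)) {
    bn[[i]]$running_mean <- st$bn[[i]]$rm
    bn[[i]]$running_var <- st$bn[[i]]$rv
  }
  model$state$rng <- st$rng_state
  model
}
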