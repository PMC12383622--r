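# Layer constructors. Each layer is an environment with a named list of
# trainable `ag_param`s in $params, optional child layers in $sub, and a
# $fwd(x, training) closure. Parameters are initialized from the R RNG, so
# builds are reproducible under set.seed().

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$sub <- list()
  class(e) <- "akb_layer"
  e
}

# He-style fan-in initialization for a (kh, kw, ci, co) kernel
init_kernel <- function(kh, kw, ci, co, gain = 2) {
  sd <- sqrt(gain / (kh * kw * ci))
  array(stats::rnorm(kh * kw * ci * co, sd = sd), c(kh, kw, ci, co))
}

#' @keywords internal
nn_collect_params <- function(layer, out = NULL) {
  if (is.null(out)) out <- list()
  for (p in layer$params) out[[length(out) + 1L]] <- p
  for (s in layer$sub) out <- nn_collect_params(s, out)
  out
}

# Conv2d (no bias) + BatchNorm + optional SiLU — the network's basic block
nn_conv <- function(ci, co, k = 3, stride = 1, act = TRUE) {
  l <- new_layer("conv")
  l$params$w <- ag_param(init_kernel(k, k, ci, co))
  l$params$gamma <- ag_param(rep(1, co))
  l$params$beta <- ag_param(rep(0, co))
  l$running_mean <- rep(0, co)
  l$running_var <- rep(1, co)
  l$bn_momentum <- 0.1
  pad <- (k - 1L) %/% 2L
  l$fwd <- function(x, training = FALSE) {
    y <- op_conv2d(x, l$params$w, stride = stride, pad = pad)
    y <- op_batchnorm(y, l$params$gamma, l$params$beta, l, training)
    if (act) op_silu(y) else y
  }
  l
}

# plain conv2d with bias (head output projections)
nn_conv_plain <- function(ci, co, k = 1, bias_init = 0) {
  l <- new_layer("conv_plain")
  l$params$w <- ag_param(init_kernel(k, k, ci, co))
  l$params$b <- ag_param(rep(bias_init, co))
  pad <- (k - 1L) %/% 2L
  l$fwd <- function(x, training = FALSE) {
    op_bias_c(op_conv2d(x, l$params$w, stride = 1, pad = pad), l$params$b)
  }
  l
}

op_bias_c <- function(x, b) {
  d <- dim(x$val)
  bcast <- array(rep(rep(b$val, each = d[1] * d[2]), d[4]), d)
  ag_node(x$val + bcast, list(x, b), function(g) {
    m <- matrix(g, nrow = d[1] * d[2])
    db <- as.numeric(rowsum(colSums(m), rep(seq_len(d[3]), times = d[4])))
    list(g, db)
  })
}

nn_bottleneck <- function(c, shortcut = TRUE) {
  l <- new_layer("bottleneck")
  l$sub$cv1 <- nn_conv(c, c, 3)
  l$sub$cv2 <- nn_conv(c, c, 3)
  l$fwd <- function(x, training = FALSE) {
    y <- l$sub$cv2$fwd(l$sub$cv1$fwd(x, training), training)
    if (shortcut) op_add(x, y) else y
  }
  l
}

# cross-stage partial block with n bottlenecks
nn_c2f <- function(c1, c2, n = 1, shortcut = FALSE) {
  l <- new_layer("c2f")
  ch <- c2 %/% 2L
  l$sub$cv1 <- nn_conv(c1, 2L * ch, 1)
  l$sub$cv2 <- nn_conv((2L + n) * ch, c2, 1)
  for (i in seq_len(n)) l$sub[[paste0("m", i)]] <- nn_bottleneck(ch, shortcut)
  l$fwd <- function(x, training = FALSE) {
    y <- l$sub$cv1$fwd(x, training)
    a <- op_slice_c(y, seq_len(ch))
    b <- op_slice_c(y, ch + seq_len(ch))
    parts <- list(a, b)
    cur <- b
    for (i in seq_len(n)) {
      cur <- l$sub[[paste0("m", i)]]$fwd(cur, training)
      parts[[length(parts) + 1L]] <- cur
    }
    l$sub$cv2$fwd(op_concat_c(parts), training)
  }
  l
}

nn_sppf <- function(c1, c2, k = 5) {
  l <- new_layer("sppf")
  ch <- c1 %/% 2L
  l$sub$cv1 <- nn_conv(c1, ch, 1)
  l$sub$cv2 <- nn_conv(4L * ch, c2, 1)
  pad <- (k - 1L) %/% 2L
  l$fwd <- function(x, training = FALSE) {
    y <- l$sub$cv1$fwd(x, training)
    p1 <- op_maxpool(y, k, stride = 1, pad = pad)
    p2 <- op_maxpool(p1, k, stride = 1, pad = pad)
    p3 <- op_maxpool(p2, k, stride = 1, pad = pad)
    l$sub$cv2$fwd(op_concat_c(list(y, p1, p2, p3)), training)
  }
  l
}

# depthwise-separable convolution: dw 3x3 + BN, pw 1x1 + BN, SiLU
nn_dwsep <- function(c) {
  l <- new_layer("dwsep")
  l$params$wd <- ag_param(array(stats::rnorm(9 * c, sd = sqrt(2 / 9)), c(3, 3, c)))
  l$params$gd <- ag_param(rep(1, c))
  l$params$bd <- ag_param(rep(0, c))
  l$running_mean <- rep(0, c)
  l$running_var <- rep(1, c)
  l$bn_momentum <- 0.1
  l$sub$pw <- nn_conv(c, c, 1, act = TRUE)
  l$fwd <- function(x, training = FALSE) {
    y <- op_dwconv(x, l$params$wd, stride = 1, pad = 1)
    y <- op_batchnorm(y, l$params$gd, l$params$bd, l, training)
    l$sub$pw$fwd(y, training)
  }
  l
}

# learnable fast-normalized fusion over a fixed number of inputs
nn_fusion <- function(n_inputs, eps = 1e-4) {
  l <- new_layer("fusion")
  l$params$w <- ag_param(rep(1, n_inputs))
  l$fwd_multi <- function(inputs, training = FALSE) op_wfusion(inputs, l$params$w, eps)
  l
}

# Adaptive-kernel convolution: a 3x3 convolution predicts a (2N)-channel
# offset field; the input is resampled bilinearly at grid-expansion
# coordinates displaced by the offsets; a 1x1 aggregation convolution
# collapses the N sampled copies; BN + SiLU finish the block.
# Offset weights start at zero so the initial layer samples the fixed grid.
nn_akconv <- function(ci, co, N = 3, stride = 1, offset_kernel = 3) {
  l <- new_layer("akconv")
  l$params$w_off <- ag_param(array(0, c(offset_kernel, offset_kernel, ci, 2L * N)))
  l$params$w_agg <- ag_param(init_kernel(1, 1, ci * N, co))
  l$params$gamma <- ag_param(rep(1, co))
  l$params$beta <- ag_param(rep(0, co))
  l$running_mean <- rep(0, co)
  l$running_var <- rep(1, co)
  l$bn_momentum <- 0.1
  l$pn <- initial_coordinates(N)
  opad <- (offset_kernel - 1L) %/% 2L
  l$fwd <- function(x, training = FALSE) {
    off <- op_conv2d(x, l$params$w_off, stride = stride, pad = opad)
    smp <- op_ak_sample(x, off, l$pn, stride = stride)
    y <- op_conv2d(smp, l$params$w_agg, stride = 1, pad = 0)
    y <- op_batchnorm(y, l$params$gamma, l$params$beta, l, training)
    op_silu(y)
  }
  l
}

# transpose convolution 2x2 stride 2 (proto-mask upsampling), implemented as
# four 1x1 convolutions interleaved on the doubled raster
nn_convtranspose2 <- function(ci, co) {
  l <- new_layer("convt2")
  for (d in 1:4) l$params[[paste0("w", d)]] <- ag_param(init_kernel(1, 1, ci, co))
  l$params$b <- ag_param(rep(0, co))
  l$fwd <- function(x, training = FALSE) {
    ys <- lapply(1:4, function(d) op_conv2d(x, l$params[[paste0("w", d)]], 1, 0))
    op_bias_c(op_interleave2(ys), l$params$b)
  }
  l
}

# assemble (2H, 2W) from four (H, W) quadrant-phase maps
op_interleave2 <- function(ys) {
  d <- dim(ys[[1]]$val)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  oi <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4)
    out[seq(oi[[k]][1], 2 * d[1], 2), seq(oi[[k]][2], 2 * d[2], 2), , ] <- ys[[k]]$val
  ag_node(out, ys, function(g) {
    lapply(1:4, function(k)
      g[seq(oi[[k]][1], 2 * d[1], 2), seq(oi[[k]][2], 2 * d[2], 2), , , drop = FALSE])
  })
}

# ---- optimizer --------------------------------------------------------------

#' Stochastic gradient descent step with momentum and weight decay
#' @keywords internal
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$val
    if (is.null(p$momentum)) p$momentum <- 0 * p$val
    p$momentum <- momentum * p$momentum - lr * g
    p$val <- p$val + p$momentum
  }
  invisible(NULL)
}
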