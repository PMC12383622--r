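# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Activations are `ag_node` environments holding a value, an accumulated
# gradient, parent links, and a backward closure. The graph is rebuilt on
# every forward pass; trainable leaves are created with ag_param() and keep
# their gradients across the backward sweep until ag_zero_grad().

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

#' Create an autograd node
#'
#' @param val numeric array or vector value.
#' @param parents list of parent `ag_node`s this value was computed from.
#' @param backfn function(grad) returning a list of gradients, one per parent.
#' @return an object of class `ag_node`.
#' @keywords internal
ag_node <- function(val, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  n$id <- .ag_counter$n
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "ag_node"
  n
}

#' Create a trainable leaf node
#' @param val initial numeric array.
#' @keywords internal
ag_param <- function(val) {
  n <- ag_node(val)
  n$is_param <- TRUE
  n$momentum <- NULL
  n
}

#' Constant (non-trainable) leaf node
#' @keywords internal
ag_const <- function(val) ag_node(val)

ag_is_node <- function(x) inherits(x, "ag_node")

.ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Reverse sweep from a scalar root
#'
#' Accumulates gradients into every reachable node; parameter nodes keep
#' theirs for the optimizer.
#' @param root `ag_node` holding a scalar value.
#' @keywords internal
ag_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  # iterative post-order DFS -> topological order
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$expanded) {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- nd
    } else if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, expanded = TRUE)
      for (p in nd$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
    }
  }
  root$grad <- 1
  for (i in seq_len(ntopo)) {
    nd <- topo[[ntopo - i + 1L]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents))
      if (!is.null(gs[[k]])) .ag_accum(nd$parents[[k]], gs[[k]])
    if (is.null(nd$is_param)) nd$grad <- NULL  # free activation gradients
  }
  invisible(root)
}

#' Clear parameter gradients
#' @param params list of `ag_node` parameters.
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and structural ops ----------------------------------------

op_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

op_scale <- function(a, s) {
  ag_node(a$val * s, list(a), function(g) list(g * s))
}

op_silu <- function(a) {
  sg <- 1 / (1 + exp(-a$val))
  ag_node(a$val * sg, list(a), function(g) list(g * (sg * (1 + a$val * (1 - sg)))))
}

op_sigmoid <- function(a) {
  sg <- 1 / (1 + exp(-a$val))
  ag_node(sg, list(a), function(g) list(g * sg * (1 - sg)))
}

op_relu <- function(a) {
  m <- a$val > 0
  ag_node(a$val * m, list(a), function(g) list(g * m))
}

# concatenate along the channel axis (dim 3 of H,W,C,B)
op_concat_c <- function(nodes) {
  dims <- lapply(nodes, function(n) dim(n$val))
  cs <- vapply(dims, `[`, numeric(1), 3)
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (k in seq_along(nodes)) {
    out[, , at + seq_len(cs[k]), ] <- nodes[[k]]$val
    at <- at + cs[k]
  }
  ag_node(out, nodes, function(g) {
    res <- vector("list", length(nodes))
    at <- 0L
    for (k in seq_along(nodes)) {
      res[[k]] <- g[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    res
  })
}

op_slice_c <- function(a, idx) {
  d <- dim(a$val)
  ag_node(a$val[, , idx, , drop = FALSE], list(a), function(g) {
    dx <- array(0, d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

# ---- compiled-kernel ops ----------------------------------------------------

op_conv2d <- function(x, w, stride = 1L, pad = 0L) {
  out <- cpp_conv2d_fwd(x$val, w$val, as.integer(stride), as.integer(pad))
  ag_node(out, list(x, w), function(g) {
    dim(g) <- dim(out)
    r <- cpp_conv2d_bwd(x$val, w$val, g, as.integer(stride), as.integer(pad))
    list(r$dx, r$dw)
  })
}

op_dwconv <- function(x, w, stride = 1L, pad = 1L) {
  out <- cpp_dwconv_fwd(x$val, w$val, as.integer(stride), as.integer(pad))
  ag_node(out, list(x, w), function(g) {
    dim(g) <- dim(out)
    r <- cpp_dwconv_bwd(x$val, w$val, g, as.integer(stride), as.integer(pad))
    list(r$dx, r$dw)
  })
}

op_maxpool <- function(x, k, stride = k, pad = 0L) {
  r <- cpp_maxpool_fwd(x$val, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$val)
  ag_node(r$out, list(x), function(g) {
    dim(g) <- dim(r$out)
    list(cpp_maxpool_bwd(as.integer(xd), r$argmax, g))
  })
}

op_upsample2 <- function(x) {
  out <- cpp_upsample2_fwd(x$val)
  xd <- dim(x$val)
  ag_node(out, list(x), function(g) {
    dim(g) <- dim(out)
    list(cpp_upsample2_bwd(as.integer(xd), g))
  })
}

op_ak_sample <- function(x, off, pn, stride = 1L) {
  out <- cpp_ak_sample_fwd(x$val, off$val, pn, as.integer(stride))
  ag_node(out, list(x, off), function(g) {
    dim(g) <- dim(out)
    r <- cpp_ak_sample_bwd(x$val, off$val, pn, as.integer(stride), g)
    list(r$dx, r$doff)
  })
}

# ---- batch normalization ----------------------------------------------------

# Per-channel batch norm over (H, W, B). `layer` is an environment carrying
# running_mean / running_var / momentum; updated only when training = TRUE.
op_batchnorm <- function(x, gamma, beta, layer, training, eps = 1e-5) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  m <- matrix(x$val, nrow = H * W)            # (HW, C*B)
  cidx <- rep(seq_len(C), times = B)
  if (training) {
    csum <- colSums(m)
    mu <- as.numeric(rowsum(csum, cidx)) / (H * W * B)
    csq <- colSums(m * m)
    ex2 <- as.numeric(rowsum(csq, cidx)) / (H * W * B)
    v <- pmax(ex2 - mu^2, 0)
    layer$running_mean <- (1 - layer$bn_momentum) * layer$running_mean + layer$bn_momentum * mu
    layer$running_var <- (1 - layer$bn_momentum) * layer$running_var + layer$bn_momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  istd <- 1 / sqrt(v + eps)
  mu_e <- mu[cidx]; istd_e <- istd[cidx]
  xhat <- sweep(sweep(m, 2, mu_e, "-"), 2, istd_e, "*")
  g_e <- gamma$val[cidx]; b_e <- beta$val[cidx]
  out <- sweep(sweep(xhat, 2, g_e, "*"), 2, b_e, "+")
  dim(out) <- d
  ag_node(out, list(x, gamma, beta), function(gr) {
    dim(gr) <- NULL
    gm <- matrix(gr, nrow = H * W)
    dbeta <- as.numeric(rowsum(colSums(gm), cidx))
    dgamma <- as.numeric(rowsum(colSums(gm * xhat), cidx))
    if (training) {
      nchan <- H * W * B
      dxhat <- sweep(gm, 2, g_e, "*")
      s1 <- as.numeric(rowsum(colSums(dxhat), cidx))[cidx]
      s2 <- as.numeric(rowsum(colSums(dxhat * xhat), cidx))[cidx]
      dx <- sweep(dxhat - s1 / nchan - xhat * (s2 / nchan), 2, istd_e, "*")
    } else {
      dx <- sweep(sweep(gm, 2, g_e, "*"), 2, istd_e, "*")
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# ---- fast-normalized weighted fusion ----------------------------------------

# O = sum_i relu(w_i) F_i / (eps + sum_j relu(w_j)); inputs share one shape.
op_wfusion <- function(inputs, w, eps = 1e-4) {
  a <- pmax(w$val, 0)
  S <- eps + sum(a)
  out <- array(0, dim(inputs[[1]]$val))
  for (i in seq_along(inputs)) if (a[i] != 0) out <- out + a[i] * inputs[[i]]$val
  out <- out / S
  ag_node(out, c(inputs, list(w)), function(g) {
    res <- vector("list", length(inputs) + 1L)
    dw <- numeric(length(a))
    go <- sum(g * out)
    for (i in seq_along(inputs)) {
      res[[i]] <- g * (a[i] / S)
      dw[i] <- if (w$val[i] > 0) (sum(g * inputs[[i]]$val) - go) / S else 0
    }
    res[[length(inputs) + 1L]] <- dw
    res
  })
}

# ---- reductions and losses on gathered values -------------------------------

# Gather head channels at spatial cells. `cells` is an n x 3 matrix of
# (h, w, b) 1-based indices; result is an n x C matrix node.
op_gather_cells <- function(x, cells) {
  d <- dim(x$val)
  n <- nrow(cells)
  out <- matrix(0, n, d[3])
  for (c in seq_len(d[3]))
    out[, c] <- x$val[cbind(cells[, 1], cells[, 2], c, cells[, 3])]
  ag_node(out, list(x), function(g) {
    dx <- array(0, d)
    for (c in seq_len(d[3]))
      dx[cbind(cells[, 1], cells[, 2], c, cells[, 3])] <-
        dx[cbind(cells[, 1], cells[, 2], c, cells[, 3])] + g[, c]
    list(dx)
  })
}

# distribution-focal decode: logits (n, 4*nbins) -> expected distances (n, 4)
op_dfl_decode <- function(x, nbins) {
  v <- x$val
  n <- nrow(v)
  out <- matrix(0, n, 4)
  probs <- array(0, c(n, nbins, 4))
  ks <- seq_len(nbins) - 1
  for (s in 1:4) {
    l <- v[, (s - 1) * nbins + seq_len(nbins), drop = FALSE]
    l <- l - apply(l, 1, max)
    e <- exp(l)
    p <- e / rowSums(e)
    probs[, , s] <- p
    out[, s] <- p %*% ks
  }
  ag_node(out, list(x), function(g) {
    dx <- matrix(0, n, 4 * nbins)
    for (s in 1:4) {
      p <- probs[, , s]
      # d expectation / d logit_j = p_j * (k_j - expectation)
      dx[, (s - 1) * nbins + seq_len(nbins)] <-
        p * (matrix(ks, n, nbins, byrow = TRUE) - out[, s]) * g[, s]
    }
    list(dx)
  })
}

# mean binary cross-entropy with logits; `weight` multiplies per-element terms
op_bce_logits <- function(logits, target, weight = NULL, reduction = "mean") {
  z <- logits$val
  # stable: max(z,0) - z*t + log(1+exp(-|z|))
  l <- pmax(z, 0) - z * target + log1p(exp(-abs(z)))
  if (!is.null(weight)) l <- l * weight
  nrm <- if (reduction == "mean") length(z) else 1
  ag_node(sum(l) / nrm, list(logits), function(g) {
    d <- (1 / (1 + exp(-z)) - target)
    if (!is.null(weight)) d <- d * weight
    list(g * d / nrm)
  })
}

# sum of squared errors, optionally scaled
op_sse <- function(pred, target, scale = 1) {
  d <- pred$val - target
  ag_node(scale * sum(d * d), list(pred), function(g) list(g * scale * 2 * d))
}

op_sum_scalar <- function(nodes) {
  ag_node(sum(vapply(nodes, function(n) n$val, numeric(1))), nodes,
          function(g) rep(list(g), length(nodes)))
}

# stack matrix nodes by rows
op_rowbind <- function(nodes) {
  ns <- vapply(nodes, function(n) nrow(n$val), numeric(1))
  out <- do.call(rbind, lapply(nodes, function(n) n$val))
  ag_node(out, nodes, function(g) {
    at <- 0
    res <- vector("list", length(nodes))
    for (k in seq_along(nodes)) {
      res[[k]] <- g[at + seq_len(ns[k]), , drop = FALSE]
      at <- at + ns[k]
    }
    res
  })
}

# affine map of matrix rows: out = x %*% T + C (T fixed, C fixed per-row)
op_matconst <- function(x, T_mat, C_mat) {
  ag_node(x$val %*% T_mat + C_mat, list(x), function(g) list(g %*% t(T_mat)))
}

# mask assembly: per positive j (image b_j), m_j = proto[,,,b_j] . coeff_j
# proto: (Hp, Wp, nm, B) node; coef: (n, nm) matrix node -> (Hp*Wp, n) node
op_mask_assemble <- function(proto, coef, img) {
  d <- dim(proto$val)
  Hp <- d[1]; Wp <- d[2]; nm <- d[3]; B <- d[4]
  n <- nrow(coef$val)
  pm <- matrix(proto$val, nrow = Hp * Wp)  # (HW, nm*B)
  out <- matrix(0, Hp * Wp, n)
  for (j in seq_len(n)) {
    cols <- (img[j] - 1) * nm + seq_len(nm)
    out[, j] <- pm[, cols, drop = FALSE] %*% coef$val[j, ]
  }
  ag_node(out, list(proto, coef), function(g) {
    dproto <- matrix(0, Hp * Wp, nm * B)
    dcoef <- matrix(0, n, nm)
    for (j in seq_len(n)) {
      cols <- (img[j] - 1) * nm + seq_len(nm)
      dproto[, cols] <- dproto[, cols] + outer(g[, j], coef$val[j, ])
      dcoef[j, ] <- crossprod(pm[, cols, drop = FALSE], g[, j])
    }
    dim(dproto) <- d
    list(dproto, dcoef)
  })
}
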