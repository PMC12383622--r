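# Assembly of the segmentation network variants.
#
# The baseline is the familiar small single-stage segmentation layout: CSP
# backbone with C2f blocks and SPPF, PAN-FPN neck (upsample + concat + C2f,
# strided-conv downsampling), and a decoupled head with distribution-focal
# box regression, one-vs-all classification, per-detection mask
# coefficients, and a prototype-mask branch.
#
# The full variant ("akb_full") replaces the neck with a bidirectional
# weighted-fusion pyramid: each level is projected to a common fusion width,
# four fusion nodes (P4td, P3out, P4out, P5out) combine their input paths by
# fast-normalized weighted fusion, and each node's post-fusion transform is
# an adaptive-kernel convolution (N = 3, stride 1, no bias) followed by a
# depthwise-separable convolution. The intermediate ablation variant
# "plus_bifpn_softnms" uses the same pyramid with C2f as the node transform.
# Soft-NMS is an inference-time setting and contributes no parameters.

#' Model specification
#'
#' @param variant one of `"baseline_s_seg"`, `"plus_softnms"`,
#'   `"plus_bifpn_softnms"`, `"akb_full"` — the ablation ladder from plain
#'   baseline to BiFPN neck + AKConv node transforms + Soft-NMS.
#' @param num_classes number of object categories (single "cell" class by
#'   default).
#' @param input_size square input resolution in pixels (multiple of 32).
#' @param width_mult,depth_mult channel and block-depth scaling of the
#'   backbone family (0.5 / 0.33 reproduce the small "s" model).
#' @param bifpn_channels common fusion width of the bidirectional pyramid.
#'   The default (328) makes the assembled variants match the reference
#'   complexity of the model family this package reimplements (11.8 M
#'   baseline, 10.4 M full variant); it scales freely for desk-size models.
#' @param bifpn_layers number of stacked bidirectional fusion repeats.
#' @param fusion_eps stabilizer of the fast-normalized fusion.
#' @param akconv_placement where adaptive-kernel convolutions replace C2f
#'   blocks: `"neck"` (default, the full variant's operating point),
#'   `"backbone"`, or `"both"`.
#' @param akconv_n number of AKConv sampling points (N).
#' @param reg_max number of distribution-focal bins per box side.
#' @param num_mask_coeffs mask-coefficient count shared with the prototype
#'   branch.
#' @param in_channels image channels fed to the stem (grayscale input is
#'   replicated to 3).
#' @return a list of class `akb_model_spec`.
#' @export
model_spec <- function(variant = c("baseline_s_seg", "plus_softnms",
                                   "plus_bifpn_softnms", "akb_full"),
                       num_classes = 1L, input_size = 640L,
                       width_mult = 0.5, depth_mult = 1 / 3,
                       bifpn_channels = 328L, bifpn_layers = 1L,
                       fusion_eps = 1e-4,
                       akconv_placement = c("neck", "backbone", "both"),
                       akconv_n = 3L, reg_max = 16L, num_mask_coeffs = 32L,
                       in_channels = 3L) {
  variant <- match.arg(variant)
  akconv_placement <- match.arg(akconv_placement)
  if (input_size %% 32 != 0) stop("input_size must be a multiple of 32")
  ch <- pmax(4L, as.integer(round(c(64, 128, 256, 512, 1024) * width_mult)))
  depths <- pmax(1L, as.integer(round(c(3, 6, 6, 3) * depth_mult)))
  p3 <- ch[3]
  spec <- list(
    variant = variant, num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    width_mult = width_mult, depth_mult = depth_mult,
    channels = ch, depths = depths, neck_depth = max(1L, as.integer(round(3 * depth_mult))),
    bifpn_channels = as.integer(bifpn_channels),
    bifpn_layers = as.integer(bifpn_layers), fusion_eps = fusion_eps,
    akconv_placement = akconv_placement, akconv_n = as.integer(akconv_n),
    reg_max = as.integer(reg_max), nm = as.integer(num_mask_coeffs),
    npr = max(8L, as.integer(round(256 * width_mult))),
    head_box_width = max(16L, p3 %/% 4L, 4L * as.integer(reg_max)),
    head_cls_width = max(p3, min(as.integer(num_classes), 100L)),
    head_coef_width = max(p3 %/% 4L, as.integer(num_mask_coeffs)),
    in_channels = as.integer(in_channels),
    use_bifpn = variant %in% c("plus_bifpn_softnms", "akb_full"),
    use_softnms = variant != "baseline_s_seg",
    strides = c(8L, 16L, 32L))
  if (variant == "akb_full") spec$akconv_placement <- "neck"
  class(spec) <- "akb_model_spec"
  spec
}

# choose the neck node transform for a variant
.neck_transform <- function(spec, cin, cout) {
  use_ak <- spec$variant == "akb_full" && spec$akconv_placement %in% c("neck", "both")
  if (use_ak) nn_akconv(cin, cout, N = spec$akconv_n, stride = 1)
  else nn_c2f(cin, cout, spec$neck_depth, shortcut = FALSE)
}

.backbone_stage <- function(spec, c, n) {
  if (spec$akconv_placement %in% c("backbone", "both") &&
      spec$variant == "akb_full")
    nn_akconv(c, c, N = spec$akconv_n, stride = 1)
  else nn_c2f(c, c, n, shortcut = TRUE)
}

#' Build a segmentation model
#'
#' Instantiates all layers with seeded random initialization; the same spec
#' and seed always produce bit-identical parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer RNG seed for parameter initialization.
#' @return an object of class `akb_model`.
#' @export
build_model <- function(spec = model_spec(), seed = 0L) {
  set.seed(seed)
  ch <- spec$channels
  root <- new_layer("model")
  bb <- new_layer("backbone")
  bb$sub$stem1 <- nn_conv(spec$in_channels, ch[1], 3, stride = 2)
  bb$sub$stem2 <- nn_conv(ch[1], ch[2], 3, stride = 2)
  bb$sub$s2 <- .backbone_stage(spec, ch[2], spec$depths[1])
  bb$sub$down3 <- nn_conv(ch[2], ch[3], 3, stride = 2)
  bb$sub$s3 <- .backbone_stage(spec, ch[3], spec$depths[2])
  bb$sub$down4 <- nn_conv(ch[3], ch[4], 3, stride = 2)
  bb$sub$s4 <- .backbone_stage(spec, ch[4], spec$depths[3])
  bb$sub$down5 <- nn_conv(ch[4], ch[5], 3, stride = 2)
  bb$sub$s5 <- .backbone_stage(spec, ch[5], spec$depths[4])
  bb$sub$sppf <- nn_sppf(ch[5], ch[5])
  root$sub$backbone <- bb

  nk <- new_layer("neck")
  if (!spec$use_bifpn) {
    nk$sub$td4 <- nn_c2f(ch[5] + ch[4], ch[4], spec$neck_depth, FALSE)
    nk$sub$td3 <- nn_c2f(ch[4] + ch[3], ch[3], spec$neck_depth, FALSE)
    nk$sub$dn3 <- nn_conv(ch[3], ch[3], 3, stride = 2)
    nk$sub$bu4 <- nn_c2f(ch[3] + ch[4], ch[4], spec$neck_depth, FALSE)
    nk$sub$dn4 <- nn_conv(ch[4], ch[4], 3, stride = 2)
    nk$sub$bu5 <- nn_c2f(ch[4] + ch[5], ch[5], spec$neck_depth, FALSE)
    head_ch <- ch[3:5]
  } else {
    W <- spec$bifpn_channels
    nk$sub$proj3 <- nn_conv(ch[3], W, 1, act = FALSE)
    nk$sub$proj4 <- nn_conv(ch[4], W, 1, act = FALSE)
    nk$sub$proj5 <- nn_conv(ch[5], W, 1, act = FALSE)
    for (r in seq_len(spec$bifpn_layers)) {
      pre <- paste0("r", r, "_")
      nk$sub[[paste0(pre, "f4td")]] <- nn_fusion(2, spec$fusion_eps)
      nk$sub[[paste0(pre, "t4td")]] <- .neck_transform(spec, W, W)
      nk$sub[[paste0(pre, "d4td")]] <- nn_dwsep(W)
      nk$sub[[paste0(pre, "f3")]] <- nn_fusion(2, spec$fusion_eps)
      nk$sub[[paste0(pre, "t3")]] <- .neck_transform(spec, W, W)
      nk$sub[[paste0(pre, "d3")]] <- nn_dwsep(W)
      nk$sub[[paste0(pre, "f4")]] <- nn_fusion(3, spec$fusion_eps)
      nk$sub[[paste0(pre, "t4")]] <- .neck_transform(spec, W, W)
      nk$sub[[paste0(pre, "d4")]] <- nn_dwsep(W)
      nk$sub[[paste0(pre, "f5")]] <- nn_fusion(2, spec$fusion_eps)
      nk$sub[[paste0(pre, "t5")]] <- .neck_transform(spec, W, W)
      nk$sub[[paste0(pre, "d5")]] <- nn_dwsep(W)
    }
    head_ch <- rep(spec$bifpn_channels, 3)
  }
  root$sub$neck <- nk

  hd <- new_layer("head")
  cb <- spec$head_box_width; cc <- spec$head_cls_width; cm <- spec$head_coef_width
  for (i in 1:3) {
    hd$sub[[paste0("box", i, "a")]] <- nn_conv(head_ch[i], cb, 3)
    hd$sub[[paste0("box", i, "b")]] <- nn_conv(cb, cb, 3)
    hd$sub[[paste0("box", i, "c")]] <- nn_conv_plain(cb, 4L * spec$reg_max, 1)
    hd$sub[[paste0("cls", i, "a")]] <- nn_conv(head_ch[i], cc, 3)
    hd$sub[[paste0("cls", i, "b")]] <- nn_conv(cc, cc, 3)
    hd$sub[[paste0("cls", i, "c")]] <- nn_conv_plain(cc, spec$num_classes, 1,
                                                     bias_init = -4)
    hd$sub[[paste0("coef", i, "a")]] <- nn_conv(head_ch[i], cm, 3)
    hd$sub[[paste0("coef", i, "b")]] <- nn_conv(cm, cm, 3)
    hd$sub[[paste0("coef", i, "c")]] <- nn_conv_plain(cm, spec$nm, 1)
  }
  hd$sub$proto1 <- nn_conv(head_ch[1], spec$npr, 3)
  hd$sub$proto_up <- nn_convtranspose2(spec$npr, spec$npr)
  hd$sub$proto2 <- nn_conv(spec$npr, spec$npr, 3)
  hd$sub$proto3 <- nn_conv(spec$npr, spec$nm, 1)
  root$sub$head <- hd

  model <- list(spec = spec, root = root, seed = as.integer(seed),
                params = nn_collect_params(root),
                state = new.env(parent = emptyenv()))
  class(model) <- "akb_model"
  model
}

# backbone forward: returns pyramid nodes P3 (stride 8), P4 (16), P5 (32)
.backbone_fwd <- function(model, x, training) {
  b <- model$root$sub$backbone$sub
  y <- b$stem2$fwd(b$stem1$fwd(x, training), training)
  y <- b$s2$fwd(y, training)
  y <- b$s3$fwd(b$down3$fwd(y, training), training)
  p3 <- y
  y <- b$s4$fwd(b$down4$fwd(p3, training), training)
  p4 <- y
  y <- b$s5$fwd(b$down5$fwd(p4, training), training)
  p5 <- b$sppf$fwd(y, training)
  list(p3, p4, p5)
}

.neck_fwd <- function(model, pyr, training) {
  nk <- model$root$sub$neck$sub
  spec <- model$spec
  if (!spec$use_bifpn) {
    t4 <- nk$td4$fwd(op_concat_c(list(op_upsample2(pyr[[3]]), pyr[[2]])), training)
    o3 <- nk$td3$fwd(op_concat_c(list(op_upsample2(t4), pyr[[1]])), training)
    o4 <- nk$bu4$fwd(op_concat_c(list(nk$dn3$fwd(o3, training), t4)), training)
    o5 <- nk$bu5$fwd(op_concat_c(list(nk$dn4$fwd(o4, training), pyr[[3]])), training)
    return(list(o3, o4, o5))
  }
  q3 <- nk$proj3$fwd(pyr[[1]], training)
  q4 <- nk$proj4$fwd(pyr[[2]], training)
  q5 <- nk$proj5$fwd(pyr[[3]], training)
  for (r in seq_len(spec$bifpn_layers)) {
    pre <- paste0("r", r, "_")
    nd <- function(nm) nk[[paste0(pre, nm)]]
    p4td <- nd("d4td")$fwd(nd("t4td")$fwd(
      nd("f4td")$fwd_multi(list(q4, op_upsample2(q5)), training), training), training)
    o3 <- nd("d3")$fwd(nd("t3")$fwd(
      nd("f3")$fwd_multi(list(q3, op_upsample2(p4td)), training), training), training)
    o4 <- nd("d4")$fwd(nd("t4")$fwd(
      nd("f4")$fwd_multi(list(q4, p4td, op_maxpool(o3, 2, 2, 0)), training),
      training), training)
    o5 <- nd("d5")$fwd(nd("t5")$fwd(
      nd("f5")$fwd_multi(list(q5, op_maxpool(o4, 2, 2, 0)), training),
      training), training)
    q3 <- o3; q4 <- o4; q5 <- o5
  }
  list(q3, q4, q5)
}

.head_fwd <- function(model, feats, training) {
  hd <- model$root$sub$head$sub
  levels <- lapply(1:3, function(i) {
    f <- feats[[i]]
    list(
      box = hd[[paste0("box", i, "c")]]$fwd(
        hd[[paste0("box", i, "b")]]$fwd(
          hd[[paste0("box", i, "a")]]$fwd(f, training), training), training),
      cls = hd[[paste0("cls", i, "c")]]$fwd(
        hd[[paste0("cls", i, "b")]]$fwd(
          hd[[paste0("cls", i, "a")]]$fwd(f, training), training), training),
      coef = hd[[paste0("coef", i, "c")]]$fwd(
        hd[[paste0("coef", i, "b")]]$fwd(
          hd[[paste0("coef", i, "a")]]$fwd(f, training), training), training))
  })
  proto <- hd$proto3$fwd(hd$proto2$fwd(hd$proto_up$fwd(
    hd$proto1$fwd(feats[[1]], training), training), training), training)
  list(levels = levels, proto = proto)
}

#' Full network forward pass (autograd nodes)
#'
#' @param model an `akb_model`.
#' @param x numeric array `H x W x C x B` (input-letterboxed batch).
#' @param training logical; batch-norm mode.
#' @return list with per-level head outputs and the prototype node.
#' @keywords internal
model_forward <- function(model, x, training = FALSE) {
  xn <- if (ag_is_node(x)) x else ag_const(x)
  feats <- .neck_fwd(model, .backbone_fwd(model, xn, training), training)
  .head_fwd(model, feats, training)
}

#' @export
print.akb_model <- function(x, ...) {
  cat(sprintf("akb_model <%s>  params: %.1f K  input: %d  classes: %d\n",
              x$spec$variant, count_parameters(x, "K"),
              x$spec$input_size, x$spec$num_classes))
  invisible(x)
}

#' Trainable-parameter accounting across the ablation ladder
#'
#' Builds each requested variant at the given spec scale and reports its
#' trainable-parameter count in thousands. Soft-NMS adds no parameters, so
#' `plus_softnms` equals the baseline by construction.
#'
#' @param variants character vector of variant names.
#' @param ... forwarded to [model_spec()].
#' @return data frame with `variant` and `params_k`.
#' @export
parameter_ladder <- function(variants = c("baseline_s_seg", "plus_softnms",
                                          "plus_bifpn_softnms", "akb_full"),
                             ...) {
  rows <- lapply(variants, function(v) {
    m <- build_model(model_spec(variant = v, ...), seed = 0L)
    k <- count_parameters(m, "K")
    rm(m)
    data.frame(variant = v, params_k = k)
  })
  do.call(rbind, rows)
}
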