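# Bidirectional feature pyramid: fast-normalized fusion, resizing, and a
# plain-array single-repeat pyramid pass usable outside the trained network.

#' Fast-normalized weighted feature fusion
#'
#' Computes `O = sum_i(w_i * F_i) / (eps + sum_j w_j)` elementwise. Raw
#' weights are rectified at zero before normalization, so the effective
#' coefficients lie in `[0, 1)` and the epsilon keeps the denominator away
#' from zero even when every weight vanishes.
#'
#' @param inputs list of numeric arrays of identical shape.
#' @param weights numeric vector, one weight per input.
#' @param eps small positive stabilizer.
#' @return numeric array of the common input shape.
#' @examples
#' fast_normalized_fusion(list(2, 4), c(1, 1))  # 6 / 2.0001
#' @export
fast_normalized_fusion <- function(inputs, weights, eps = 1e-4) {
  if (length(inputs) < 1L) stop("at least one input required")
  if (length(weights) != length(inputs))
    stop("need exactly one weight per input")
  shp <- dim(inputs[[1]])
  for (f in inputs[-1])
    if (!identical(dim(f), shp) || length(f) != length(inputs[[1]]))
      stop("fusion inputs must share one shape")
  w <- pmax(weights, 0)
  out <- 0 * inputs[[1]]
  for (i in seq_along(inputs)) out <- out + w[i] * inputs[[i]]
  out / (eps + sum(w))
}

#' Resize a feature map to a target spatial size
#'
#' Enlargement uses nearest-neighbour upsampling; reduction uses repeated
#' stride-2 max pooling. Resizing to the map's own size is the identity.
#'
#' @param feature numeric array `H x W` or `H x W x C` or `H x W x C x B`.
#' @param target_spatial integer pair (height, width).
#' @return resized array with the same trailing dimensions.
#' @export
resize_to <- function(feature, target_spatial) {
  th <- target_spatial[1]; tw <- target_spatial[2]
  if (th < 1 || tw < 1) stop("target dims must be >= 1")
  d0 <- dim(feature)
  if (is.null(d0)) d0 <- c(length(feature), 1L)
  x <- feature
  dim(x) <- c(d0[1], d0[2], prod(d0[-(1:2)], 1), 1)
  while (dim(x)[1] > th || dim(x)[2] > tw)
    x <- cpp_maxpool_fwd(x, 2L, 2L, 0L)$out
  while (dim(x)[1] < th || dim(x)[2] < tw)
    x <- cpp_upsample2_fwd(x)
  if (!identical(as.integer(dim(x)[1:2]), as.integer(c(th, tw))))
    stop("target size must be reachable by factor-2 steps from the input size")
  dim(x) <- c(th, tw, d0[-(1:2)])
  x
}

# the fusion graph on three levels; returns, for each produced node, the
# (source, path) inputs it fuses. Node P5td would have a single input edge
# and is therefore absent, per the single-input-node removal rule.
bifpn_node_table <- function() {
  list(
    p4td  = list(inputs = c("p4in", "p5in_up"),           n = 2L),
    p3out = list(inputs = c("p3in", "p4td_up"),           n = 2L),
    p4out = list(inputs = c("p4in", "p4td", "p3out_dn"),  n = 3L),
    p5out = list(inputs = c("p5in", "p4out_dn"),          n = 2L)
  )
}

#' One bidirectional pyramid pass on plain arrays
#'
#' Runs the top-down then bottom-up weighted-fusion graph on a 3-level
#' pyramid. All levels must share the channel count; spatial sizes must halve
#' per level. With `transform = "identity"` each node is exactly the fast
#' normalized fusion of its input paths, which makes the graph checkable by
#' hand; `transform` may also be a `function(x, level_index)` applied after
#' each fusion.
#'
#' @param pyramid list of 3 numeric arrays (finest first), `H_l x W_l x C`.
#' @param weights named list of fusion weight vectors with entries `p4td` (2),
#'   `p3out` (2), `p4out` (3), `p5out` (2); defaults to all-ones.
#' @param eps fusion stabilizer.
#' @param transform `"identity"` or a function applied after each fusion.
#' @return list of 3 arrays with the input shapes.
#' @export
bifpn_layer <- function(pyramid, weights = NULL, eps = 1e-4,
                        transform = "identity") {
  stopifnot(length(pyramid) == 3L)
  pyramid <- lapply(pyramid, function(p) {
    if (is.null(dim(p))) dim(p) <- c(length(p), 1L)
    if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
    p
  })
  nodes <- bifpn_node_table()
  if (is.null(weights))
    weights <- lapply(nodes, function(nd) rep(1, nd$n))
  tf <- if (identical(transform, "identity")) function(x, l) x else transform
  sz <- function(p) dim(p)[1:2]
  p3 <- pyramid[[1]]; p4 <- pyramid[[2]]; p5 <- pyramid[[3]]
  p4td <- tf(fast_normalized_fusion(
    list(p4, resize_to(p5, sz(p4))), weights$p4td, eps), 2L)
  p3out <- tf(fast_normalized_fusion(
    list(p3, resize_to(p4td, sz(p3))), weights$p3out, eps), 1L)
  p4out <- tf(fast_normalized_fusion(
    list(p4, p4td, resize_to(p3out, sz(p4))), weights$p4out, eps), 2L)
  p5out <- tf(fast_normalized_fusion(
    list(p5, resize_to(p4out, sz(p5))), weights$p5out, eps), 3L)
  list(p3out, p4out, p5out)
}
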