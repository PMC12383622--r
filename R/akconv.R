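# Adaptive-kernel convolution: public API around the nn_akconv layer.

#' Initial sampling coordinates for an adaptive kernel
#'
#' Lays out `N` sampling points by grid expansion from the top-left origin:
#' with `k = max(1, round(sqrt(N)))`, full rows of width `k` are filled
#' row-major starting at (0,0), followed by a partial row holding the
#' remaining `N %% k` points.
#'
#' @param N number of sampling points (>= 1).
#' @return integer matrix `N x 2` of (row, col) offsets; first row is (0,0).
#' @examples
#' initial_coordinates(3)   # (0,0), (0,1), (1,0)
#' initial_coordinates(5)   # two full rows of 2, then (2,0)
#' @export
initial_coordinates <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  N <- as.integer(N)
  k <- max(1L, as.integer(round(sqrt(N))))
  rows <- N %/% k
  rem <- N %% k
  coords <- cbind(rep(seq_len(rows) - 1L, each = k), rep(seq_len(k) - 1L, rows))
  if (rem > 0L) coords <- rbind(coords, cbind(rows, seq_len(rem) - 1L))
  dimnames(coords) <- list(NULL, c("row", "col"))
  coords
}

#' Closed-form trainable-parameter count of an AKConv block
#'
#' Offset predictor (`C_in * offset_kernel^2 * 2N`, no bias) + aggregation
#' convolution (`C_in * N * C_out`, no bias) + batch-norm scale and shift
#' (`2 * C_out`). Affine in `N`, unlike the quadratic growth of a `k x k`
#' square kernel.
#'
#' @param c_in,c_out channel counts.
#' @param N number of sampling points.
#' @param offset_kernel kernel size of the offset-predicting convolution.
#' @return integer parameter count.
#' @export
akconv_param_count <- function(c_in, c_out, N, offset_kernel = 3) {
  stopifnot(c_in >= 1, c_out >= 1, N >= 1, offset_kernel >= 1)
  c_in * offset_kernel^2 * 2 * N + c_in * N * c_out + 2 * c_out
}

#' Build an adaptive-kernel convolution layer
#'
#' @param c_in,c_out input/output channels.
#' @param num_param number of sampling points `N` (the operating point used
#'   throughout the assembled network is `N = 3`).
#' @param stride sampling stride.
#' @param seed optional seed for the aggregation-weight initialization.
#' @return an `akb_layer` usable with [akconv_forward()].
#' @export
akconv_layer <- function(c_in, c_out, num_param = 3, stride = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn_akconv(c_in, c_out, N = num_param, stride = stride)
}

#' Run an adaptive-kernel convolution forward
#'
#' Predicts the offset field (shape `H' x W' x 2N x B`), resamples the input
#' bilinearly at `P0 + Pn + offset` with border clamping, aggregates the `N`
#' sampled maps with a 1x1 convolution, and applies batch norm + SiLU.
#'
#' @param layer layer from [akconv_layer()].
#' @param feature numeric array `H x W x C_in x B` (a single map `H x W x C_in`
#'   is promoted to batch size 1).
#' @param training logical; use batch statistics and update running stats.
#' @return numeric array `H' x W' x C_out x B`.
#' @export
akconv_forward <- function(layer, feature, training = FALSE) {
  if (length(dim(feature)) == 3L) dim(feature) <- c(dim(feature), 1L)
  out <- layer$fwd(ag_const(feature), training = training)
  out$val
}

#' Offset field predicted by an AKConv layer for a given feature map
#' @inheritParams akconv_forward
#' @return numeric array `H' x W' x 2N x B` of interleaved (drow, dcol) offsets.
#' @export
akconv_offsets <- function(layer, feature) {
  if (length(dim(feature)) == 3L) dim(feature) <- c(dim(feature), 1L)
  pad <- (dim(layer$params$w_off$val)[1] - 1L) %/% 2L
  st <- environment(layer$fwd)$stride
  cpp_conv2d_fwd(feature, layer$params$w_off$val, as.integer(st), as.integer(pad))
}

#' Bilinear interpolation with border clamp
#'
#' Reads a 2-D map at fractional (row, col) positions, 0-based; positions
#' outside the raster are clamped to the border.
#'
#' @param x numeric matrix.
#' @param pts numeric `n x 2` matrix of 0-based (row, col) positions.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(x, pts) {
  cpp_bilinear_at(as.matrix(x), matrix(as.numeric(pts), ncol = 2))
}
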