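# Microscopy image enhancement: contrast-limited adaptive histogram
# equalization followed (by default) by Gaussian smoothing. Images are
# numeric arrays in [0, 1] (H x W, or H x W x 3), or integer rasters in
# 0..255; the input representation is preserved.

.img_to_bins <- function(x) {
  if (is.integer(x) || max(x) > 1 + 1e-9) as.integer(round(x))
  else as.integer(round(x * 255))
}

.bins_to_img <- function(q, like) {
  if (is.integer(like) || max(like) > 1 + 1e-9) q else q / 255
}

#' Clip a histogram at a contrast-limit ceiling
#'
#' The ceiling is `clip_limit * n / 256` (at least 1 count), where `n` is the
#' pixel count behind the histogram; excess mass is redistributed uniformly
#' over all bins, preserving the total.
#'
#' @param hist numeric length-256 histogram.
#' @param clip_limit positive contrast-limiting factor.
#' @return list with `hist` (clipped + redistributed) and `ceiling`.
#' @export
clip_histogram <- function(hist, clip_limit) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  n <- sum(hist)
  ceiling_v <- max(1, clip_limit * n / length(hist))
  excess <- sum(pmax(hist - ceiling_v, 0))
  h <- pmin(hist, ceiling_v) + excess / length(hist)
  list(hist = h, ceiling = ceiling_v)
}

# equalization mapping 0..255 -> 0..255 from a (possibly clipped) histogram
.hist_mapping <- function(h) {
  cdf <- cumsum(h)
  n <- cdf[length(cdf)]
  pos <- cdf[cdf > 0]
  cdfmin <- if (length(pos)) pos[1] else n
  if (n <= cdfmin) return(0:255)  # single occupied bin: identity
  as.integer(round((pmax(cdf - cdfmin, 0)) / (n - cdfmin) * 255))
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `tile_grid` of non-overlapping sub-regions;
#' each gets its own clipped-histogram equalization mapping, and every pixel
#' is remapped by bilinear interpolation between the mappings of the four
#' nearest tile centers, which removes tile-border seams. RGB input is
#' equalized on its luminance channel and the chromatic ratios are preserved.
#'
#' @param img numeric matrix/array in `[0, 1]`, or integer in 0..255;
#'   `H x W` or `H x W x 3`.
#' @param clip_limit positive contrast-limiting factor (histogram ceiling is
#'   `clip_limit` times the uniform bin height).
#' @param tile_grid integer pair (rows, cols) of sub-regions.
#' @return enhanced image, same shape and representation.
#' @export
clahe <- function(img, clip_limit = 2.0, tile_grid = c(8, 8)) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  tile_grid <- as.integer(tile_grid)
  if (any(tile_grid < 1)) stop("tile_grid entries must be >= 1")
  if (length(dim(img)) == 3L) {
    y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    y2 <- clahe(y, clip_limit, tile_grid)
    ratio <- ifelse(y > 1e-8, y2 / pmax(y, 1e-8), 0)
    out <- img
    for (c in 1:3) out[, , c] <- pmin(pmax(img[, , c] * ratio, 0), 1)
    return(out)
  }
  H <- nrow(img); W <- ncol(img)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  if (H < tr || W < tc) stop("image smaller than one tile per grid cell")
  q <- .img_to_bins(img)
  dim(q) <- c(H, W)
  rb <- round(seq(0, H, length.out = tr + 1))
  cb <- round(seq(0, W, length.out = tc + 1))
  maps <- matrix(0L, 256, tr * tc)
  centers_r <- (rb[-1] + rb[-(tr + 1)] + 1) / 2   # 1-based tile center rows
  centers_c <- (cb[-1] + cb[-(tc + 1)] + 1) / 2
  for (ti in seq_len(tr)) for (tj in seq_len(tc)) {
    tile <- q[(rb[ti] + 1):rb[ti + 1], (cb[tj] + 1):cb[tj + 1]]
    h <- tabulate(tile + 1L, nbins = 256L)
    maps[, ti + (tj - 1) * tr] <- .hist_mapping(clip_histogram(h, clip_limit)$hist)
  }
  # bilinear blend between the four surrounding tile-center mappings
  interp_axis <- function(pos, centers) {
    k <- length(centers)
    i0 <- findInterval(pos, centers)
    i0 <- pmin(pmax(i0, 1L), max(k - 1L, 1L))
    i1 <- pmin(i0 + 1L, k)
    denom <- centers[i1] - centers[i0]
    w1 <- ifelse(denom > 0, (pos - centers[i0]) / denom, 0)
    w1 <- pmin(pmax(w1, 0), 1)
    list(i0 = i0, i1 = i1, w1 = w1)
  }
  ra <- interp_axis(seq_len(H), centers_r)
  ca <- interp_axis(seq_len(W), centers_c)
  qv <- as.vector(q) + 1L
  ri0 <- rep(ra$i0, W); ri1 <- rep(ra$i1, W); rw <- rep(ra$w1, W)
  ci0 <- rep(ca$i0, each = H); ci1 <- rep(ca$i1, each = H); cw <- rep(ca$w1, each = H)
  lut <- function(ri, ci) maps[cbind(qv, ri + (ci - 1L) * tr)]
  outq <- (1 - rw) * (1 - cw) * lut(ri0, ci0) + (1 - rw) * cw * lut(ri0, ci1) +
    rw * (1 - cw) * lut(ri1, ci0) + rw * cw * lut(ri1, ci1)
  outq <- round(outq)
  out <- .bins_to_img(outq, img)
  dim(out) <- c(H, W)
  if (is.integer(img)) storage.mode(out) <- "integer"
  out
}

.gauss_kernel1d <- function(k, sigma) {
  r <- (k - 1) / 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized 2-D Gaussian kernel (applied separably);
#' borders are handled by reflection, so constants are preserved exactly.
#' When `sigma` is omitted it follows the usual kernel-size rule
#' `0.3 * ((k - 1)/2 - 1) + 0.8`.
#'
#' @param img numeric matrix/array (`H x W` or `H x W x C`).
#' @param kernel odd positive kernel size in pixels.
#' @param sigma positive standard deviation in pixels.
#' @return smoothed image, same shape.
#' @export
gaussian_blur <- function(img, kernel = 3, sigma = NULL) {
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel must be odd and positive")
  if (is.null(sigma)) sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  if (sigma <= 0) stop("sigma must be positive")
  if (length(dim(img)) == 3L) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- gaussian_blur(img[, , c], kernel, sigma)
    return(out)
  }
  w <- .gauss_kernel1d(kernel, sigma)
  r <- (kernel - 1) / 2
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1, 2 - idx, idx)
    ifelse(idx > n, 2 * n - idx, idx)
  }
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W)
  for (o in -r:r) tmp <- tmp + w[o + r + 1] * img[reflect(seq_len(H) + o, H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (o in -r:r) out <- out + w[o + r + 1] * tmp[, reflect(seq_len(W) + o, W), drop = FALSE]
  out
}

#' Preprocessing configuration
#'
#' @param clip_limit CLAHE contrast-limiting factor (> 0).
#' @param tile_grid integer (rows, cols) tile grid.
#' @param blur_kernel odd Gaussian kernel size in pixels.
#' @param blur_sigma Gaussian standard deviation; `NULL` derives it from the
#'   kernel size.
#' @param order `"clahe_then_blur"` (default) or `"blur_then_clahe"`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_limit = 2.0, tile_grid = c(8, 8),
                              blur_kernel = 3, blur_sigma = NULL,
                              order = c("clahe_then_blur", "blur_then_clahe")) {
  order <- match.arg(order)
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (blur_kernel %% 2 == 0 || blur_kernel < 1) stop("blur_kernel must be odd")
  if (!is.null(blur_sigma) && blur_sigma <= 0) stop("blur_sigma must be positive")
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma,
                 order = order), class = "preprocess_config")
}

#' Enhance an image with CLAHE and Gaussian smoothing
#'
#' Applies the two stages in the configured order; deterministic, and applied
#' identically whether images are destined for training or inference.
#'
#' @param img image as for [clahe()].
#' @param cfg a [preprocess_config()].
#' @return enhanced image.
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  a <- function(x) clahe(x, cfg$clip_limit, cfg$tile_grid)
  b <- function(x) gaussian_blur(x, cfg$blur_kernel, cfg$blur_sigma)
  if (cfg$order == "clahe_then_blur") b(a(img)) else a(b(img))
}
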