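# Reading and writing raster images. PNG through the png package; TIFF
# through the tiff package when present. Images are numeric arrays in
# [0, 1]; 16-bit input is rescaled to the 8-bit range by min-max scaling.

#' Read a PNG or TIFF image
#'
#' @param path file path; format chosen by extension.
#' @param normalize16 rescale 16-bit content to `[0, 1]` by min-max scaling.
#' @return numeric array in `[0, 1]` (`H x W` grayscale or `H x W x 3`).
#' @export
read_image <- function(path, normalize16 = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF files")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1]    # gray+alpha
  # 16-bit sources decode to [0,1] already but may occupy a narrow range
  if (normalize16 && max(img) > 0 && diff(range(img)) > 0 && max(img) < 0.5)
    img <- (img - min(img)) / diff(range(img))
  img
}

#' Write an image to PNG or TIFF
#'
#' @param img numeric array in `[0, 1]`.
#' @param path destination path; format chosen by extension.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF files")
    tiff::writeTIFF(img, path)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Convert an RGB array to grayscale luminance
#' @param img `H x W` or `H x W x 3` array.
#' @return `H x W` matrix.
#' @export
as_gray <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else img
}
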