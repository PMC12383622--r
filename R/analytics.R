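# Confluence and cell-count analytics computed from instance masks.

#' Cell confluence of an image
#'
#' Percentage of the image area covered by the union of the instance masks;
#' pixels covered by several overlapping cells count once.
#'
#' @param masks list of logical matrices aligned to the image raster.
#' @param image_shape integer (height, width).
#' @return confluence percentage in `[0, 100]`.
#' @export
confluence <- function(masks, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  if (H < 1 || W < 1) stop("image area must be positive")
  if (length(masks) == 0L) return(0)
  u <- matrix(FALSE, H, W)
  for (m in masks) {
    if (!identical(dim(m), as.integer(c(H, W))) && !identical(dim(m), c(H, W)))
      stop("mask raster does not match image_shape")
    u <- u | (m > 0)
  }
  100 * sum(u) / (H * W)
}

#' Number of segmented cells in a result
#'
#' @param result a segmentation result (list with `masks`), or a plain list
#'   of masks.
#' @return non-negative integer instance count.
#' @export
cell_count <- function(result) {
  if (!is.null(result$masks)) length(result$masks) else length(result)
}

#' Per-image confluence report
#'
#' @param result segmentation result with `masks` (and optionally
#'   `image_id`).
#' @param image_shape integer (height, width).
#' @return list with `confluence` (percent), `cell_count`, `covered_pixels`,
#'   `total_pixels`, `image_id`.
#' @export
confluence_report <- function(result, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  conf <- confluence(result$masks, image_shape)
  list(image_id = if (is.null(result$image_id)) NA else result$image_id,
       confluence = conf,
       cell_count = cell_count(result),
       covered_pixels = as.integer(round(conf / 100 * H * W)),
       total_pixels = as.integer(H * W))
}
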