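# Seeded generator of bright-field-like cell scenes with exact ground truth.
#
# Cells are star-shaped deformed ellipses: an ellipse (random radius,
# eccentricity, orientation) whose boundary radius is modulated by a
# low-order Fourier series, giving the irregular outlines of near-spherical
# cells with deformed subpopulations. The generator stresses the four
# failure axes of real cultures: irregular shape, dense adhesion (cells
# placed touching/overlapping), multi-scale size spread, and unclear
# boundaries (blur + noise + low contrast). Instance masks are rasterized
# before blur and noise are applied, so ground truth is unambiguous.

#' Synthetic scene configuration
#'
#' @param size square image size in pixels.
#' @param n_cells integer range (min, max) of cells per scene.
#' @param radius range of mean cell radii in pixels; sampled log-uniformly to
#'   emulate the order-of-magnitude size spread of cultured cells
#'   (10-100 um under a 20x objective at the default 640 px scale).
#' @param eccentricity range of axis ratios (1 = circular).
#' @param adhesion probability that a new cell is placed touching or
#'   overlapping an existing one.
#' @param min_sep minimum boundary separation in pixels between non-adherent
#'   cells.
#' @param irregularity standard deviation of the Fourier boundary
#'   perturbation (fraction of the radius).
#' @param blur_sigma boundary-blur Gaussian sigma in pixels.
#' @param contrast mean foreground/background intensity difference (cells
#'   are darker than the background, as in bright-field culture images).
#' @param noise_sd additive Gaussian noise sigma (intensity units).
#' @param poisson also apply Poisson (shot) noise at 8-bit scale.
#' @param gradient amplitude of a linear background illumination gradient.
#' @param bg background base intensity.
#' @param seed integer seed; the scene is fully determined by it.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(size = 640L, n_cells = c(8L, 24L), radius = c(4, 40),
                         eccentricity = c(1, 1.6), adhesion = 0.3,
                         min_sep = 2, irregularity = 0.12, blur_sigma = 1.2,
                         contrast = 0.35, noise_sd = 0.03, poisson = FALSE,
                         gradient = 0.08, bg = 0.72, seed = 0L) {
  stopifnot(size >= 16, n_cells[1] <= n_cells[2], radius[1] <= radius[2],
            eccentricity[1] <= eccentricity[2],
            adhesion >= 0, adhesion <= 1, blur_sigma >= 0)
  structure(as.list(environment()), class = "scene_config")
}

#' Easy, well-separated study conditions for desk-scale training
#'
#' Small images, disjoint round-ish cells, mild noise: the configuration the
#' scaled-down end-to-end training check runs on.
#'
#' @param size image size (64-160 px regime).
#' @param seed scene seed.
#' @return a [scene_config()].
#' @export
easy_scene_config <- function(size = 128L, seed = 0L) {
  scene_config(size = size, n_cells = c(3L, 7L), radius = c(9, 18),
               eccentricity = c(1, 1.3), adhesion = 0, min_sep = 6,
               irregularity = 0.06, blur_sigma = 0.8, contrast = 0.4,
               noise_sd = 0.02, poisson = FALSE, gradient = 0.05,
               bg = 0.75, seed = seed)
}

# membership test of pixel positions (px = col, py = row; 1-based centers)
.cell_inside <- function(cell, px, py) {
  dx <- px - cell$cx; dy <- py - cell$cy
  u <- dx * cos(cell$phi) + dy * sin(cell$phi)
  v <- -dx * sin(cell$phi) + dy * cos(cell$phi)
  us <- u / (cell$r * sqrt(cell$ecc))
  vs <- v / (cell$r / sqrt(cell$ecc))
  rho <- sqrt(us^2 + vs^2)
  th <- atan2(vs, us)
  rr <- 1 + cell$a[1] * cos(2 * th + cell$ph[1]) +
    cell$a[2] * cos(3 * th + cell$ph[2]) + cell$a[3] * cos(4 * th + cell$ph[3])
  rho <= rr
}

.cell_polygon <- function(cell, nv = 64L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  rr <- 1 + cell$a[1] * cos(2 * th + cell$ph[1]) +
    cell$a[2] * cos(3 * th + cell$ph[2]) + cell$a[3] * cos(4 * th + cell$ph[3])
  us <- rr * cos(th) * cell$r * sqrt(cell$ecc)
  vs <- rr * sin(th) * cell$r / sqrt(cell$ecc)
  x <- cell$cx + us * cos(cell$phi) - vs * sin(cell$phi)
  y <- cell$cy + us * sin(cell$phi) + vs * cos(cell$phi)
  cbind(x = x, y = y)
}

.cell_maxr <- function(cell) cell$r * sqrt(cell$ecc) * (1 + sum(abs(cell$a)))

#' Generate one synthetic cell scene
#'
#' Renders the configured number of deformed-ellipse cells, places them with
#' the configured adhesion behaviour, records per-instance masks and
#' polygons, then applies boundary blur, the illumination gradient, and
#' noise. When a cell cannot be placed within a bounded number of retries
#' the scene is returned with fewer cells and a warning.
#'
#' @param cfg a [scene_config()].
#' @return list of class `synthetic_scene` with elements `image` (matrix in
#'   `[0,1]`), `instances` (list of logical masks), `polygons` (list of
#'   `n x 2` matrices, (x, y) normalized to `[0,1]`), `boxes`
#'   (`n x 4` matrix, x1/y1/x2/y2 pixel coords), `coverage` (analytic union
#'   coverage fraction from a supersampled raster), and `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  set.seed(cfg$seed)
  S <- cfg$size
  n_target <- if (cfg$n_cells[1] == cfg$n_cells[2]) cfg$n_cells[1]
              else sample(cfg$n_cells[1]:cfg$n_cells[2], 1L)
  cells <- list()
  for (i in seq_len(n_target)) {
    placed <- FALSE
    for (try in 1:60) {
      r <- exp(stats::runif(1, log(cfg$radius[1]), log(cfg$radius[2])))
      ecc <- stats::runif(1, cfg$eccentricity[1], cfg$eccentricity[2])
      a <- pmax(pmin(stats::rnorm(3, 0, cfg$irregularity), 0.3), -0.3)
      if (sum(abs(a)) > 0.45) a <- a * 0.45 / sum(abs(a))
      cell <- list(r = r, ecc = ecc, phi = stats::runif(1, 0, pi),
                   a = a, ph = stats::runif(3, 0, 2 * pi))
      mr <- .cell_maxr(cell)
      adhere <- length(cells) > 0 && stats::runif(1) < cfg$adhesion
      if (adhere) {
        j <- sample(length(cells), 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- (cells[[j]]$r + r) * stats::runif(1, 0.75, 1.0)
        cell$cx <- cells[[j]]$cx + dist * cos(ang)
        cell$cy <- cells[[j]]$cy + dist * sin(ang)
        if (cell$cx < mr + 1 || cell$cx > S - mr || cell$cy < mr + 1 ||
            cell$cy > S - mr) next
      } else {
        if (S - 2 * mr - 2 <= 0) next
        cell$cx <- stats::runif(1, mr + 1, S - mr)
        cell$cy <- stats::runif(1, mr + 1, S - mr)
        ok <- TRUE
        for (old in cells) {
          d <- sqrt((cell$cx - old$cx)^2 + (cell$cy - old$cy)^2)
          if (d < .cell_maxr(old) + mr + cfg$min_sep) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      cells[[length(cells) + 1L]] <- cell
      placed <- TRUE
      break
    }
    if (!placed)
      warning(sprintf("placed %d of %d cells; scene too crowded",
                      length(cells), n_target))
  }
  # rasterize masks (pre-blur, pre-noise ground truth)
  instances <- vector("list", length(cells))
  boxes <- matrix(0, length(cells), 4)
  colnames(boxes) <- c("x1", "y1", "x2", "y2")
  img <- matrix(0, S, S)
  gdir <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  gy <- matrix(rep(seq_len(S), S), S, S)          # row index
  img[] <- cfg$bg + cfg$gradient *
    ((gx / S - 0.5) * cos(gdir) + (gy / S - 0.5) * sin(gdir))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    mr <- .cell_maxr(cell)
    x0 <- max(1L, floor(cell$cx - mr)); x1 <- min(S, ceiling(cell$cx + mr))
    y0 <- max(1L, floor(cell$cy - mr)); y1 <- min(S, ceiling(cell$cy + mr))
    pxs <- x0:x1; pys <- y0:y1
    px <- matrix(rep(pxs, each = length(pys)), length(pys))
    py <- matrix(rep(pys, length(pxs)), length(pys))
    ins <- .cell_inside(cell, px, py)
    m <- matrix(FALSE, S, S)
    m[cbind(as.vector(py)[ins], as.vector(px)[ins])] <- TRUE
    instances[[i]] <- m
    w <- which(m, arr.ind = TRUE)
    boxes[i, ] <- c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
    depth <- cfg$contrast * stats::runif(1, 0.85, 1.15)
    tex <- stats::rnorm(sum(ins), 0, 0.02)
    img[cbind(as.vector(py)[ins], as.vector(px)[ins])] <-
      img[cbind(as.vector(py)[ins], as.vector(px)[ins])] - depth + tex
  }
  # analytic coverage from a 2x supersampled union raster
  ss <- 2L
  cov_hits <- matrix(FALSE, S * ss, S * ss)
  for (cell in cells) {
    mr <- .cell_maxr(cell)
    xs <- max(1L, floor((cell$cx - mr) * ss)):min(S * ss, ceiling((cell$cx + mr) * ss))
    ys <- max(1L, floor((cell$cy - mr) * ss)):min(S * ss, ceiling((cell$cy + mr) * ss))
    px <- matrix(rep((xs - 0.5) / ss + 0.5, each = length(ys)), length(ys))
    py <- matrix(rep((ys - 0.5) / ss + 0.5, length(xs)), length(ys))
    ins <- .cell_inside(cell, px, py)
    cov_hits[cbind(as.vector(row(px)) + ys[1] - 1L,
                   as.vector(col(px)) + xs[1] - 1L)] <-
      cov_hits[cbind(as.vector(row(px)) + ys[1] - 1L,
                     as.vector(col(px)) + xs[1] - 1L)] | as.vector(ins)
  }
  coverage <- mean(cov_hits)
  if (cfg$blur_sigma > 0) {
    k <- max(3L, 2L * ceiling(2 * cfg$blur_sigma) + 1L)
    img <- gaussian_blur(img, k, cfg$blur_sigma)
  }
  if (cfg$noise_sd > 0) img <- img + matrix(stats::rnorm(S * S, 0, cfg$noise_sd), S, S)
  if (cfg$poisson) img <- matrix(stats::rpois(S * S, pmax(img, 0) * 255) / 255, S, S)
  img <- pmin(pmax(img, 0), 1)
  polys <- lapply(cells, function(cell) {
    p <- .cell_polygon(cell)
    cbind(x = pmin(pmax(p[, 1] / S, 0), 1), y = pmin(pmax(p[, 2] / S, 0), 1))
  })
  structure(list(image = img, instances = instances, polygons = polys,
                 boxes = boxes, coverage = coverage, config = cfg,
                 n_cells = length(cells)),
            class = "synthetic_scene")
}

#' Generate a seeded dataset of scenes
#'
#' @param n number of scenes.
#' @param cfg template [scene_config()]; each scene gets its own derived seed.
#' @param seed master seed.
#' @return list of `synthetic_scene`s.
#' @export
synth_dataset <- function(n, cfg = scene_config(), seed = 0L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- seeds[i]
    generate_scene(ci)
  })
}

# rasterize a polygon given in pixel coordinates to a logical mask
polygon_to_mask <- function(poly_px, H, W) {
  x0 <- max(1L, floor(min(poly_px[, 1]))); x1 <- min(W, ceiling(max(poly_px[, 1])))
  y0 <- max(1L, floor(min(poly_px[, 2]))); y1 <- min(H, ceiling(max(poly_px[, 2])))
  m <- matrix(FALSE, H, W)
  if (x1 < x0 || y1 < y0) return(m)
  pxs <- x0:x1; pys <- y0:y1
  pts <- cbind(rep(pxs, each = length(pys)), rep(pys, length(pxs)))
  ins <- mgcv::in.out(rbind(poly_px, poly_px[1, , drop = FALSE]),
                      cbind(as.numeric(pts[, 1]), as.numeric(pts[, 2])))
  m[cbind(pts[ins, 2], pts[ins, 1])] <- TRUE
  m
}

#' Write scenes as an image + label dataset
#'
#' Images are written as PNG under `images/`; labels either as one polygon
#' text file per image under `labels/` (class index followed by the
#' normalized x,y polygon, one instance per line) or as a single COCO-style
#' `annotations.json` with polygon segmentations.
#'
#' @param scenes list of `synthetic_scene`s.
#' @param out_dir output directory (created).
#' @param format `"yolo_seg"` or `"coco"`.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(scenes, out_dir, format = c("yolo_seg", "coco")) {
  format <- match.arg(format)
  if (length(scenes) == 0L) stop("no scenes to write")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (format == "yolo_seg")
    dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  coco_images <- list(); coco_anns <- list(); ann_id <- 0L
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    nm <- sprintf("scene_%04d", i)
    write_image(sc$image, file.path(out_dir, "images", paste0(nm, ".png")))
    S <- nrow(sc$image)
    if (format == "yolo_seg") {
      lines <- vapply(sc$polygons, function(p) {
        paste(c("0", sprintf("%.6f", as.vector(t(p)))), collapse = " ")
      }, character(1))
      writeLines(lines, file.path(out_dir, "labels", paste0(nm, ".txt")))
    } else {
      coco_images[[length(coco_images) + 1L]] <-
        list(id = i, file_name = paste0(nm, ".png"),
             height = nrow(sc$image), width = ncol(sc$image))
      for (j in seq_along(sc$polygons)) {
        ann_id <- ann_id + 1L
        pp <- sc$polygons[[j]]
        seg <- as.vector(t(cbind(pp[, 1] * ncol(sc$image), pp[, 2] * nrow(sc$image))))
        b <- sc$boxes[j, ]
        coco_anns[[length(coco_anns) + 1L]] <-
          list(id = ann_id, image_id = i, category_id = 1L,
               segmentation = list(seg),
               bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
               area = sum(sc$instances[[j]]), iscrowd = 0L)
      }
    }
  }
  if (format == "coco") {
    jsonlite::write_json(
      list(images = coco_images, annotations = coco_anns,
           categories = list(list(id = 1L, name = "cell"))),
      file.path(out_dir, "annotations.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Polygons are rasterized back to instance masks.
#'
#' @param dir dataset directory.
#' @param format `"yolo_seg"` or `"coco"`.
#' @return list of scenes: `image`, `instances`, `polygons`, `boxes`.
#' @export
read_dataset <- function(dir, format = c("yolo_seg", "coco")) {
  format <- match.arg(format)
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (format == "coco") {
    cc <- jsonlite::read_json(file.path(dir, "annotations.json"),
                              simplifyVector = FALSE)
    byimg <- split(cc$annotations,
                   vapply(cc$annotations, function(a) a$image_id, numeric(1)))
  }
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    img <- as_gray(read_image(imgs[i]))
    H <- nrow(img); W <- ncol(img)
    polys <- list()
    if (format == "yolo_seg") {
      lab <- file.path(dir, "labels",
                       sub("\\.png$", ".txt", basename(imgs[i])))
      if (file.exists(lab))
        polys <- lapply(readLines(lab), function(ln) {
          v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])[-1]
          cbind(x = v[seq(1, length(v), 2)] * W, y = v[seq(2, length(v), 2)] * H)
        })
    } else {
      anns <- byimg[[as.character(i)]]
      if (!is.null(anns))
        polys <- lapply(anns, function(a) {
          v <- as.numeric(unlist(a$segmentation[[1]]))
          cbind(x = v[seq(1, length(v), 2)], y = v[seq(2, length(v), 2)])
        })
    }
    masks <- lapply(polys, polygon_to_mask, H = H, W = W)
    keep <- vapply(masks, any, logical(1))
    masks <- masks[keep]; polys <- polys[keep]
    boxes <- t(vapply(masks, function(m) {
      w <- which(m, arr.ind = TRUE)
      c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
    }, numeric(4)))
    if (length(masks) == 0L) boxes <- matrix(0, 0, 4)
    colnames(boxes) <- c("x1", "y1", "x2", "y2")
    out[[i]] <- list(image = img, instances = masks, polygons = polys,
                     boxes = boxes)
  }
  out
}
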