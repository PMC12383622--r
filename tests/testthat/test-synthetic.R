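test_that("scene generation is bit-deterministic in the seed", {
  cfg <- scene_config(size = 96, n_cells = c(4, 8), radius = c(4, 12), seed = 42)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$instances, b$instances)
  expect_identical(a$polygons, b$polygons)
  c <- generate_scene(scene_config(size = 96, n_cells = c(4, 8),
                                   radius = c(4, 12), seed = 43))
  expect_false(identical(a$image, c$image))
})

test_that("zero adhesion with positive separation yields disjoint masks", {
  sc <- generate_scene(scene_config(size = 128, n_cells = c(5, 8),
                                    radius = c(5, 12), adhesion = 0,
                                    min_sep = 3, seed = 9))
  n <- length(sc$instances)
  expect_gte(n, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    expect_equal(sum(sc$instances[[i]] & sc$instances[[j]]), 0)
})

test_that("analytic coverage agrees with mask-union confluence within 1%", {
  for (seed in c(1, 7, 19)) {
    sc <- generate_scene(scene_config(size = 128, n_cells = c(6, 10),
                                      radius = c(5, 14), adhesion = 0.4,
                                      seed = seed))
    conf <- confluence(sc$instances, dim(sc$image))
    expect_lt(abs(conf / 100 - sc$coverage), 0.01)
  }
})

test_that("polygons are consistent with their masks", {
  sc <- generate_scene(scene_config(size = 96, n_cells = c(4, 6),
                                    radius = c(5, 12), seed = 33))
  S <- nrow(sc$image)
  for (j in seq_along(sc$instances)) {
    pm <- akbseg:::polygon_to_mask(cbind(sc$polygons[[j]][, 1] * S,
                                         sc$polygons[[j]][, 2] * S), S, S)
    expect_gte(mask_iou(pm, sc$instances[[j]]), 0.95)
  }
})

test_that("mean realized cell count tracks the configured mean", {
  cfg <- scene_config(size = 64, n_cells = c(2, 6), radius = c(3, 7),
                      adhesion = 0.2, seed = 0)
  scenes <- suppressWarnings(synth_dataset(200, cfg, seed = 5))
  counts <- vapply(scenes, function(s) s$n_cells, numeric(1))
  expect_lt(abs(mean(counts) - 4) / 4, 0.1)
})

test_that("stronger boundary blur weakens edge gradients", {
  grad_at_boundary <- function(sc) {
    img <- sc$image
    gx <- img[, -1] - img[, -ncol(img)]
    gy <- img[-1, ] - img[-nrow(img), ]
    gm <- sqrt(gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2)
    bnd <- Reduce(`|`, lapply(sc$instances, function(m) {
      inner <- m[-1, -1] & m[-nrow(m), -1] & m[-1, -ncol(m)]
      m[-nrow(m), -ncol(m)] & !inner
    }))
    mean(gm[bnd])
  }
  sharper <- 0
  for (seed in 1:20) {
    base <- scene_config(size = 80, n_cells = c(3, 5), radius = c(5, 10),
                         noise_sd = 0, blur_sigma = 0.5, seed = seed)
    soft <- base; soft$blur_sigma <- 2.5
    g1 <- grad_at_boundary(generate_scene(base))
    g2 <- grad_at_boundary(generate_scene(soft))
    expect_lt(g2, g1)
  }
})

test_that("datasets round-trip through both label formats with IoU >= 0.95", {
  scenes <- suppressWarnings(
    synth_dataset(2, scene_config(size = 96, n_cells = c(3, 5),
                                  radius = c(6, 12)), seed = 2))
  for (fmt in c("yolo_seg", "coco")) {
    dir <- file.path(tempdir(), paste0("ds_", fmt))
    unlink(dir, recursive = TRUE)
    write_dataset(scenes, dir, fmt)
    back <- read_dataset(dir, fmt)
    expect_equal(length(back), length(scenes))
    for (i in seq_along(scenes)) {
      expect_equal(length(back[[i]]$instances), length(scenes[[i]]$instances))
      for (j in seq_along(scenes[[i]]$instances))
        expect_gte(mask_iou(back[[i]]$instances[[j]], scenes[[i]]$instances[[j]]),
                   0.95)
    }
  }
  # normalized polygon coordinates stay in [0, 1]
  lab <- readLines(file.path(tempdir(), "ds_yolo_seg", "labels", "scene_0001.txt"))
  vals <- as.numeric(unlist(lapply(strsplit(lab, " "), `[`, -1)))
  expect_true(all(vals >= 0 & vals <= 1))
  # COCO schema essentials present
  cc <- jsonlite::read_json(file.path(tempdir(), "ds_coco", "annotations.json"))
  expect_true(all(c("images", "annotations", "categories") %in% names(cc)))
  expect_true(all(c("id", "image_id", "category_id", "segmentation", "bbox") %in%
                  names(cc$annotations[[1]])))
})
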