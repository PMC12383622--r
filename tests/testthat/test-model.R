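desk_scenes <- function(seeds, size = 96) {
  suppressWarnings(lapply(seeds, function(s)
    generate_scene(easy_scene_config(size = size, seed = s))))
}

test_that("model building is deterministic in spec and seed", {
  spec <- desk_model_spec()
  a <- build_model(spec, seed = 3)
  b <- build_model(spec, seed = 3)
  csum <- function(m) sum(vapply(m$params, function(p) sum(p$val^2), numeric(1)))
  expect_identical(csum(a), csum(b))
  c <- build_model(spec, seed = 4)
  expect_false(isTRUE(all.equal(csum(a), csum(c))))
  expect_error(model_spec(input_size = 100), "multiple of 32")
})

test_that("ablation ladder orders parameter counts as claimed", {
  lad <- parameter_ladder()
  counts <- setNames(lad$params_k, lad$variant)
  expect_gt(counts["plus_bifpn_softnms"], counts["baseline_s_seg"])
  expect_lt(counts["akb_full"], counts["baseline_s_seg"])
  expect_equal(counts[["plus_softnms"]], counts[["baseline_s_seg"]])
})

test_that("zero learning rate leaves parameters untouched", {
  m <- build_model(desk_model_spec(), seed = 1)
  before <- lapply(m$params, function(p) p$val)
  cfg <- desk_train_config(seed = 1, epochs = 2, batch_size = 2, lr = 0)
  train_model(m, desk_scenes(1:2), cfg)
  for (i in seq_along(before)) expect_identical(m$params[[i]]$val, before[[i]])
})

test_that("seeded optimization on a fixed batch reduces the total loss", {
  m <- build_model(desk_model_spec(), seed = 5)
  cfg <- desk_train_config(seed = 9, epochs = 50, batch_size = 2, lr = 0.02,
                           lr_final_frac = 1)
  h <- train_model(m, desk_scenes(c(11, 12)), cfg)   # 50 steps of batch 2
  expect_equal(nrow(h), 50)
  expect_lt(tail(h$loss, 1), h$loss[1])
  expect_true(all(is.finite(h$loss)))
})

test_that("resuming from a checkpoint reproduces the uninterrupted trajectory", {
  scenes <- desk_scenes(21:24)
  ck <- file.path(tempdir(), "resume.ckpt")
  m1 <- build_model(desk_model_spec(), seed = 2)
  cfg12 <- desk_train_config(seed = 4, epochs = 2, batch_size = 4,
                             lr = 0.01, lr_final_frac = 1)
  train_model(m1, scenes, cfg12, checkpoint_path = ck)
  m1b <- load_checkpoint(ck)
  cfg3 <- desk_train_config(seed = 4, epochs = 1, batch_size = 4,
                            lr = 0.01, lr_final_frac = 1)
  h_resumed <- train_model(m1b, scenes, cfg3)
  m2 <- build_model(desk_model_spec(), seed = 2)
  cfg123 <- desk_train_config(seed = 4, epochs = 3, batch_size = 4,
                              lr = 0.01, lr_final_frac = 1)
  h_full <- train_model(m2, scenes, cfg123)
  expect_equal(h_resumed$loss[1], h_full$loss[3], tolerance = 1e-10)
})

test_that("inference is deterministic and keeps detections paired with masks", {
  m <- build_model(desk_model_spec(), seed = 6)
  sc <- desk_scenes(31)[[1]]
  r1 <- predict_image(m, sc$image, conf = 0.001)
  r2 <- predict_image(m, sc$image, conf = 0.001)
  expect_identical(r1$detections, r2$detections)
  expect_equal(nrow(r1$detections), length(r1$masks))
  if (nrow(r1$detections) > 0) {
    expect_true(all(r1$detections$x1 >= 0 & r1$detections$x2 <= ncol(sc$image)))
    expect_true(all(r1$detections$y1 >= 0 & r1$detections$y2 <= nrow(sc$image)))
  }
  # a flat image through an untrained head: empty result is valid, and the
  # pairing contract still holds
  r0 <- predict_image(m, matrix(0, 96, 96), conf = 0.25)
  expect_equal(nrow(r0$detections), length(r0$masks))
})

test_that("the model overfits one scene and recovers at least 90% of instances", {
  sc <- desk_scenes(5)[[1]]
  m <- build_model(desk_model_spec(), seed = 11)
  cfg <- desk_train_config(seed = 2, epochs = 80, batch_size = 1, lr = 0.02,
                           lr_final_frac = 0.5)
  train_model(m, list(sc), cfg)
  r <- predict_image(m, sc$image, conf = 0.1)
  matched <- 0
  used <- rep(FALSE, nrow(r$detections))
  for (j in seq_len(nrow(sc$boxes))) {
    ious <- vapply(seq_len(nrow(r$detections)), function(i)
      if (used[i]) -1 else box_iou(as.numeric(r$detections[i, 1:4]),
                                   as.numeric(sc$boxes[j, ])), numeric(1))
    if (length(ious) && max(ious) >= 0.5) {
      matched <- matched + 1
      used[which.max(ious)] <- TRUE
    }
  }
  expect_gte(matched / nrow(sc$boxes), 0.9)
})
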