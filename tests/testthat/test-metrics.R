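test_that("mask IoU counts set sizes", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  c <- matrix(FALSE, 4, 4); c[1:2, 2:3] <- TRUE   # shares 2 of 4 pixels with a
  expect_equal(mask_iou(a, c), 2 / 6, tolerance = 1e-12)
  expect_error(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("precision and recall follow the count definitions", {
  expect_equal(precision_recall(c(TP = 9, FP = 1, FN = 0))[["precision"]], 0.9)
  expect_equal(precision_recall(c(TP = 9, FP = 0, FN = 3))[["recall"]], 0.75)
  expect_equal(precision_recall(c(TP = 0, FP = 0, FN = 2))[["precision"]], 0)
})

test_that("average precision reproduces hand-enumerated PR curves", {
  gt <- data.frame(image_id = 1, x1 = c(0, 20), y1 = c(0, 20),
                   x2 = c(10, 30), y2 = c(10, 30))
  # one matching prediction: AP = 1
  p1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.9)
  expect_equal(average_precision(p1, gt[1, ]), 1)
  # TP at 0.9 then a far FP at 0.8 over two GTs: envelope area 0.5
  p2 <- rbind(p1, data.frame(image_id = 1, x1 = 50, y1 = 50, x2 = 60, y2 = 60,
                             score = 0.8))
  expect_equal(average_precision(p2, gt), 0.5)
  # empty predictions give 0; perfect predictions give 1
  expect_equal(average_precision(p2[0, ], gt), 0)
  perfect <- data.frame(image_id = 1, x1 = c(0, 20), y1 = c(0, 20),
                        x2 = c(10, 30), y2 = c(10, 30), score = c(0.9, 0.8))
  expect_equal(average_precision(perfect, gt), 1)
  expect_error(average_precision(p1, gt[0, ]), "ground truth")
})

test_that("AP equals an exhaustive threshold-sweep oracle on random scenes", {
  set.seed(77)
  for (rep in 1:100) {
    n_img <- sample(1:3, 1)
    gts <- do.call(rbind, lapply(seq_len(n_img), function(i) {
      g <- random_dets(sample(1:4, 1), size = 30)
      g$score <- NULL; g$image_id <- i; g
    }))
    preds <- do.call(rbind, lapply(seq_len(n_img), function(i) {
      # predictions: jittered copies of some GTs plus random noise boxes
      g <- gts[gts$image_id == i, , drop = FALSE]
      take <- g[sample(nrow(g), sample(0:nrow(g), 1)), , drop = FALSE]
      if (nrow(take) > 0) {
        take[, 1:4] <- take[, 1:4] + matrix(runif(4 * nrow(take), -1, 1), ncol = 4)
        take$x2 <- pmax(take$x2, take$x1 + 0.5)
        take$y2 <- pmax(take$y2, take$y1 + 0.5)
      }
      noise <- random_dets(sample(0:3, 1), size = 30)
      noise$image_id <- rep(i, nrow(noise))
      take$score <- round(runif(nrow(take), 0.05, 0.999), 3)
      rbind(take, noise)
    }))
    if (nrow(preds) == 0) next
    preds$score <- round(preds$score, 3)
    ap <- average_precision(preds, gts, iou_thr = 0.5, mode = "box")
    expect_equal(ap, oracle_ap_sweep(preds, gts, 0.5), tolerance = 1e-10)
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
})

test_that("mAP50 is the mean of per-class APs", {
  expect_equal(map50(0.7), 0.7)
  expect_equal(map50(c(1, 0.5)), 0.75)
  expect_equal(map50(rep(0.37, 6)), 0.37)
  expect_error(map50(numeric(0)), "at least one")
})

test_that("paired t-test reproduces the repeated-runs worked example", {
  opt <- c(0.950, 0.946, 0.944, 0.951)
  base <- c(0.917, 0.919, 0.913, 0.915)
  r <- paired_t_test(opt, base)
  expect_equal(round(r[["t"]], 2), 16.82)
  expect_equal(r[["p"]], 0.00046, tolerance = 0.01)
  expect_equal(paired_t_test(base, base), c(t = 0, p = 1))
  expect_equal(paired_t_test(base + 0.01, base)[["t"]], Inf)
})

test_that("parameter counting matches layer arithmetic", {
  ns <- asNamespace("akbseg")
  plain <- ns$nn_conv_plain(8, 16, 3)
  expect_equal(count_parameters(plain), 8 * 9 * 16 + 16)  # kernel + bias
  expect_equal(length(plain$params$w$val), 1152)
  withbn <- ns$nn_conv(8, 16, 3)
  expect_equal(count_parameters(withbn), 1152 + 32)       # BN scale + shift
})

test_that("COCO-style evaluation of a dataset against itself is perfect", {
  scenes <- suppressWarnings(
    synth_dataset(2, scene_config(size = 96, n_cells = c(3, 5),
                                  radius = c(6, 12)), seed = 8))
  dir <- file.path(tempdir(), "coco_eval")
  unlink(dir, recursive = TRUE)
  write_dataset(scenes, dir, "coco")
  ann <- file.path(dir, "annotations.json")
  ev <- evaluate_coco(ann, ann)
  expect_equal(ev$map50_box, 1)
  expect_equal(ev$map50_mask, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})
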