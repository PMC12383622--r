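test_that("box IoU matches set arithmetic", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(box_iou(c(0, 0, 0, 2), c(1, 1, 3, 3)), "degenerate")
})

test_that("Gaussian decay follows the piecewise rule", {
  d <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(4, 4), y2 = c(4, 4),
                  score = c(0.9, 0.8))
  out <- soft_nms(d, nms_config(Nt = 0.3, sigma = 0.5, score_min = 0.001))
  expect_equal(nrow(out), 2)
  expect_equal(out$score, c(0.9, 0.8 * exp(-2)), tolerance = 1e-12)
  # below the IoU threshold both scores are untouched
  far <- data.frame(x1 = c(0, 10), y1 = c(0, 10), x2 = c(4, 14), y2 = c(4, 14),
                    score = c(0.9, 0.8))
  out2 <- soft_nms(far, nms_config(Nt = 0.3, sigma = 0.5))
  expect_equal(out2$score, c(0.9, 0.8))
  # single detection unchanged; empty input is empty, not an error
  one <- far[1, ]
  expect_equal(soft_nms(one, nms_config())$score, 0.9)
  expect_equal(nrow(soft_nms(far[0, ], nms_config())), 0)
})

test_that("scores never increase and survivors carry decayed products", {
  set.seed(31)
  for (rep in 1:10) {
    d <- random_dets(30)
    out <- soft_nms(d, nms_config(Nt = 0.3, sigma = 0.4, score_min = 0))
    expect_equal(nrow(out), nrow(d))
    m <- merge(out, d, by = c("x1", "y1", "x2", "y2"), suffixes = c("_out", "_in"))
    expect_true(all(m$score_out <= m$score_in + 1e-12))
  }
})

test_that("soft NMS matches the literal score-decay oracle on random instances", {
  set.seed(17)
  for (rep in 1:100) {
    d <- random_dets(sample(2:25, 1))
    cfg <- nms_config(Nt = 0.4, sigma = 0.5, score_min = 0.05)
    out <- soft_nms(d, cfg)
    ora <- oracle_soft_nms(d, cfg$Nt, cfg$sigma, cfg$score_min)
    expect_equal(nrow(out), nrow(ora))
    expect_equal(sort(out$score), sort(ora$score), tolerance = 1e-10)
  }
})

test_that("hard NMS equals the brute-force reference and the sigma->0 limit of soft NMS", {
  set.seed(23)
  for (rep in 1:12) {
    d <- random_dets(50)
    keep <- hard_nms(d, 0.5)
    ora_idx <- oracle_hard_nms(d, 0.5)
    expect_equal(nrow(keep), length(ora_idx))
    expect_equal(sort(keep$score), sort(d$score[ora_idx]))
    # sigma -> 0 with a positive floor reproduces the hard keep set
    soft0 <- soft_nms(d, nms_config(Nt = 0.5, sigma = 1e-9, score_min = 1e-6))
    expect_equal(sort(soft0$score), sort(keep$score), tolerance = 1e-12)
  }
  # two coincident boxes: only the higher-scoring box survives
  d2 <- data.frame(x1 = 0, y1 = 0, x2 = 3, y2 = 3, score = c(0.7, 0.6))
  expect_equal(hard_nms(d2, 0.5)$score, 0.7)
})

test_that("suppression output is invariant to input order", {
  set.seed(41)
  for (rep in 1:10) {
    d <- random_dets(40)
    d$score <- round(d$score, 1)           # force score ties
    cfg <- nms_config(Nt = 0.4, sigma = 0.5, score_min = 0.01)
    a <- soft_nms(d, cfg)
    b <- soft_nms(d[sample(nrow(d)), ], cfg)
    expect_equal(a, b)
    expect_equal(hard_nms(d, 0.5), hard_nms(d[sample(nrow(d)), ], 0.5))
  }
})
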