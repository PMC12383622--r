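test_that("CLAHE leaves a constant image constant and stays in range", {
  img <- matrix(128L, 32, 32)
  out <- clahe(img, clip_limit = 2, tile_grid = c(4, 4))
  expect_true(all(out == out[1, 1]))
  set.seed(11)
  noisy <- matrix(runif(64 * 64), 64, 64)
  enh <- clahe(noisy, 2, c(8, 8))
  expect_true(all(enh >= 0 & enh <= 1))
})

test_that("single-tile CLAHE with a large clip limit is plain histogram equalization", {
  set.seed(5)
  img <- matrix(rep(seq(0.2, 0.6, length.out = 8), each = 8), 8, 8)
  out <- clahe(img, clip_limit = 1e6, tile_grid = c(1, 1))
  expect_equal(out, oracle_histeq(img), tolerance = 1e-12)
  # and on an irregular image
  img2 <- matrix(runif(144, 0.3, 0.7), 12, 12)
  expect_equal(clahe(img2, 1e6, c(1, 1)), oracle_histeq(img2), tolerance = 1e-12)
})

test_that("histogram clipping enforces the ceiling and preserves total mass", {
  h <- tabulate(sample.int(256, 4096, replace = TRUE, prob = (1:256)^2), 256)
  cl <- clip_histogram(h, clip_limit = 2)
  base <- pmin(h, cl$ceiling)
  expect_true(all(base <= cl$ceiling))
  expect_equal(sum(cl$hist), sum(h))
  expect_true(all(cl$hist >= base))   # redistribution only adds mass
})

test_that("CLAHE validates parameters", {
  img <- matrix(runif(64), 8, 8)
  expect_error(clahe(img, clip_limit = 0), "positive")
  expect_error(clahe(img, 2, c(16, 16)), "smaller")
})

test_that("Gaussian blur matches the analytic kernel and preserves constants", {
  const <- matrix(0.4, 16, 16)
  expect_equal(gaussian_blur(const, 3, 1), const, tolerance = 1e-12)
  # impulse response equals the normalized kernel
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  out <- gaussian_blur(imp, 3, 1)
  w1 <- exp(-(-1:1)^2 / 2); w1 <- w1 / sum(w1)
  expect_equal(out[3:5, 3:5], outer(w1, w1), tolerance = 1e-12)
  expect_equal(sum(outer(w1, w1)), 1, tolerance = 1e-9)
  # reflection borders preserve the global mean of a constant-padded field
  expect_equal(mean(gaussian_blur(const, 5, 2)), mean(const), tolerance = 1e-6)
  expect_error(gaussian_blur(const, 4, 1), "odd")
})

test_that("preprocess composes the stages in order and is deterministic", {
  set.seed(9)
  img <- matrix(runif(32 * 32, 0.4, 0.6), 32, 32)
  cfg <- preprocess_config(clip_limit = 3, tile_grid = c(2, 2), blur_kernel = 3)
  out1 <- preprocess(img, cfg)
  out2 <- preprocess(img, cfg)
  expect_identical(out1, out2)
  expect_equal(out1, gaussian_blur(clahe(img, 3, c(2, 2)), 3), tolerance = 1e-12)
  cfg2 <- preprocess_config(clip_limit = 3, tile_grid = c(2, 2), blur_kernel = 3,
                            order = "blur_then_clahe")
  expect_equal(preprocess(img, cfg2), clahe(gaussian_blur(img, 3), 3, c(2, 2)),
               tolerance = 1e-12)
})

test_that("enhancement raises the contrast of a low-contrast cell scene", {
  sc <- generate_scene(scene_config(size = 64, n_cells = c(4, 6), radius = c(5, 10),
                                    contrast = 0.08, noise_sd = 0.01, seed = 21))
  out <- clahe(sc$image, 2, c(4, 4))
  expect_gt(sd(out), sd(sc$image))
})
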