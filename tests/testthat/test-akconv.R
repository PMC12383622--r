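test_that("grid-expansion coordinates follow the layout rule", {
  expect_equal(unname(initial_coordinates(1)), cbind(0L, 0L))
  expect_equal(unname(initial_coordinates(3)), rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_equal(unname(initial_coordinates(4)),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  expect_equal(unname(initial_coordinates(5)),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L), c(2L, 0L)))
  for (N in 1:12) {
    g <- initial_coordinates(N)
    expect_equal(nrow(g), N)
    expect_equal(g[1, ], c(row = 0L, col = 0L))
    expect_equal(anyDuplicated(g), 0L)
  }
  expect_error(initial_coordinates(0), "positive")
})

test_that("bilinear resampling interpolates and clamps at borders", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)           # [[1,2],[3,4]] row-major
  expect_equal(bilinear_sample(m, cbind(0.5, 0.5)), 2.5)
  expect_equal(bilinear_sample(m, cbind(-0.5, 0)), m[1, 1])
  expect_equal(bilinear_sample(m, cbind(0, 0.25)), 1.25)
  expect_equal(bilinear_sample(m, cbind(5, 5)), m[2, 2])
})

test_that("closed-form parameter count matches layer enumeration and is affine in N", {
  expect_equal(akconv_param_count(8, 16, 3, 3), 8 * 9 * 6 + 8 * 3 * 16 + 32)
  expect_equal(akconv_param_count(8, 16, 3, 3), 848)
  for (N in c(1, 3, 5, 7)) {
    lay <- akconv_layer(6, 10, num_param = N, seed = 1)
    walked <- sum(vapply(akbseg:::nn_collect_params(lay),
                         function(p) length(p$val), numeric(1)))
    expect_equal(walked, akconv_param_count(6, 10, N))
  }
  # affine: equal second differences over N
  cnt <- vapply(1:9, function(N) akconv_param_count(5, 7, N), numeric(1))
  expect_true(all(abs(diff(diff(cnt))) < 1e-9))
  # a k x k square convolution grows quadratically in k
  sq <- vapply(1:3, function(k) k^2 * 5 * 7, numeric(1))
  expect_gt(diff(diff(sq))[1], 0)
})

test_that("degenerate single-point configuration reduces to SiLU of the input", {
  lay <- akconv_layer(1, 1, num_param = 1, seed = 2)
  lay$params$w_agg$val[] <- 1          # identity aggregation
  x <- array(rnorm(25), c(5, 5, 1, 1))
  out <- akconv_forward(lay, x, training = FALSE)   # BN pass-through stats
  silu <- function(v) v / (1 + exp(-v))
  istd <- 1 / sqrt(1 + 1e-5)
  expect_equal(as.vector(out), silu(as.vector(x) * istd), tolerance = 1e-6)
})

test_that("zero-offset AKConv equals a direct gather-and-matmul oracle", {
  set.seed(4)
  lay <- akconv_layer(1, 1, num_param = 3, seed = 4)
  x <- array(rnorm(16), c(4, 4, 1, 1))
  out <- akconv_forward(lay, x)
  pn <- initial_coordinates(3)
  w <- as.vector(lay$params$w_agg$val)
  istd <- 1 / sqrt(1 + 1e-5)
  silu <- function(v) v / (1 + exp(-v))
  oracle <- matrix(0, 4, 4)
  for (i in 0:3) for (j in 0:3) {
    acc <- 0
    for (n in 1:3) {
      r <- min(max(i + pn[n, 1], 0), 3)
      c <- min(max(j + pn[n, 2], 0), 3)
      acc <- acc + w[n] * x[r + 1, c + 1, 1, 1]
    }
    oracle[i + 1, j + 1] <- silu(acc * istd)
  }
  expect_equal(out[, , 1, 1], oracle, tolerance = 1e-5)
})

test_that("offset field has the contracted shape and output stays finite", {
  lay <- akconv_layer(2, 3, num_param = 4, seed = 5)
  x <- array(rnorm(2 * 6 * 6), c(6, 6, 2, 1))
  off <- akconv_offsets(lay, x)
  expect_equal(dim(off), c(6L, 6L, 8L, 1L))
  # push huge offsets through a trained-looking layer: clamped sampling
  lay$params$w_off$val[] <- rnorm(length(lay$params$w_off$val), sd = 50)
  out <- akconv_forward(lay, x)
  expect_true(all(is.finite(out)))
  expect_equal(dim(out), c(6L, 6L, 3L, 1L))
})

test_that("strided AKConv reduces spatial dims by the stride", {
  lay <- akconv_layer(2, 2, num_param = 3, stride = 2, seed = 6)
  x <- array(rnorm(2 * 8 * 8), c(8, 8, 2, 1))
  expect_equal(dim(akconv_forward(lay, x))[1:2], c(4L, 4L))
})
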