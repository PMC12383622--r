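test_that("fast-normalized fusion matches hand-computed values", {
  expect_equal(fast_normalized_fusion(list(2, 4), c(1, 1)), 6 / 2.0001,
               tolerance = 1e-12)
  # zero weight excludes an input (up to the epsilon scale)
  expect_equal(fast_normalized_fusion(list(2, 4), c(1, 0)), 2 / 1.0001,
               tolerance = 1e-12)
  # all-zero weights guard the denominator
  expect_equal(fast_normalized_fusion(list(2, 4), c(0, 0)), 0)
  # negative raw weights are rectified
  expect_equal(fast_normalized_fusion(list(2, 4), c(1, -5)), 2 / 1.0001,
               tolerance = 1e-12)
  expect_error(fast_normalized_fusion(list(matrix(1, 2, 2), matrix(1, 3, 3)),
                                      c(1, 1)), "shape")
})

test_that("fusion output is a sub-convex combination of its inputs", {
  set.seed(8)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    ins <- lapply(seq_len(k), function(i) array(rnorm(12), c(3, 4)))
    w <- runif(k, 0, 3)
    out <- fast_normalized_fusion(ins, w)
    lo <- Reduce(pmin, ins); hi <- Reduce(pmax, ins)
    shrink <- sum(pmax(w, 0)) / (1e-4 + sum(pmax(w, 0)))
    expect_true(all(out >= pmin(lo * shrink, lo) - 1e-12))
    expect_true(all(out <= pmax(hi * shrink, hi) + 1e-12))
    expect_lt(shrink, 1)
  }
})

test_that("resize_to upsamples by replication and reduces by block max", {
  m <- matrix(1:4, 2, 2)
  up <- resize_to(m, c(4, 4))
  expect_equal(up[1:2, 1:2], matrix(m[1, 1], 2, 2))
  expect_equal(up[3:4, 3:4], matrix(m[2, 2], 2, 2))
  r <- matrix(1:16, 4, 4)
  dn <- resize_to(r, c(2, 2))
  expect_equal(dn, matrix(c(max(r[1:2, 1:2]), max(r[3:4, 1:2]),
                            max(r[1:2, 3:4]), max(r[3:4, 3:4])), 2, 2))
  expect_identical(resize_to(r, c(4, 4)), r)
})

test_that("single-repeat pyramid pass with identity transforms matches a hand-built oracle", {
  set.seed(12)
  p3 <- array(rnorm(16), c(4, 4, 1))
  p4 <- array(rnorm(4), c(2, 2, 1))
  p5 <- array(rnorm(1), c(1, 1, 1))
  out <- bifpn_layer(list(p3, p4, p5))
  eps <- 1e-4
  fuse <- function(lst) Reduce(`+`, lst) / (eps + length(lst))
  p4td <- fuse(list(p4, resize_to(p5, c(2, 2))))
  o3 <- fuse(list(p3, resize_to(p4td, c(4, 4))))
  o4 <- fuse(list(p4, p4td, resize_to(o3, c(2, 2))))
  o5 <- fuse(list(p5, resize_to(o4, c(1, 1))))
  expect_equal(out[[1]], o3, tolerance = 1e-12)
  expect_equal(out[[2]], o4, tolerance = 1e-12)
  expect_equal(out[[3]], o5, tolerance = 1e-12)
  # shapes preserved
  expect_equal(lapply(out, dim), lapply(list(p3, p4, p5), dim))
})

test_that("the fusion graph contains no single-input nodes", {
  nodes <- akbseg:::bifpn_node_table()
  expect_true(all(vapply(nodes, function(n) n$n, numeric(1)) >= 2))
  expect_false("p5td" %in% names(nodes))
})

test_that("stacking fusion repeats grows the parameter count affinely", {
  cnt <- vapply(1:3, function(L) {
    m <- build_model(model_spec(variant = "akb_full", width_mult = 0.125,
                                bifpn_channels = 16, bifpn_layers = L,
                                reg_max = 4, num_mask_coeffs = 8,
                                input_size = 96), seed = 1)
    count_parameters(m)
  }, numeric(1))
  expect_true(all(diff(cnt) > 0))
  expect_equal(diff(diff(cnt)), 0)
})
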