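test_that("confluence follows inclusion-exclusion on the mask union", {
  shape <- c(10, 10)
  expect_equal(confluence(list(), shape), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(confluence(list(half), shape), 50)
  # two 30% masks overlapping on 10% cover 50%
  a <- matrix(FALSE, 10, 10); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[3:5, ] <- TRUE
  expect_equal(confluence(list(a, b), shape), 50)
  expect_error(confluence(list(), c(0, 10)), "positive")
})

test_that("confluence is monotone, bounded, and below the mask-area sum", {
  set.seed(14)
  masks <- lapply(1:6, function(i) {
    m <- matrix(FALSE, 20, 20)
    r <- sample(1:14, 1); c <- sample(1:14, 1)
    m[r:(r + 5), c:(c + 5)] <- TRUE
    m
  })
  prev <- 0
  for (k in seq_along(masks)) {
    cur <- confluence(masks[1:k], c(20, 20))
    expect_gte(cur, prev)
    expect_lte(cur, 100)
    expect_lte(cur, sum(vapply(masks[1:k], sum, numeric(1))) / 4)
    prev <- cur
  }
})

test_that("cell count equals the number of kept instances", {
  expect_equal(cell_count(list(masks = list())), 0)
  masks <- replicate(7, matrix(TRUE, 2, 2), simplify = FALSE)
  res <- list(masks = masks, image_id = "img1")
  expect_equal(cell_count(res), 7)
  rep <- confluence_report(res, c(2, 2))
  expect_equal(rep$cell_count, length(res$masks))
  expect_equal(rep$confluence, 100)
  expect_equal(rep$covered_pixels, 4)
  expect_equal(rep$total_pixels, 4)
})

test_that("ground-truth confluence matches the generator's analytic coverage", {
  sc <- generate_scene(scene_config(size = 160, n_cells = c(8, 12),
                                    radius = c(5, 16), adhesion = 0.3, seed = 6))
  expect_lt(abs(confluence(sc$instances, dim(sc$image)) / 100 - sc$coverage), 0.01)
})
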