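test_that("classification cross-entropy matches hand-computed values", {
  b <- loss_batch(cls_target = matrix(c(1, 0), 1), cls_pred = matrix(c(1 - 1e-7, 1e-7), 1))
  expect_lt(classification_loss(b), 1e-6)
  b2 <- loss_batch(cls_target = matrix(c(1, 0), 1), cls_pred = matrix(c(0.5, 0.5), 1))
  expect_equal(classification_loss(b2), -log(0.5), tolerance = 1e-12)
  # uniform prediction over C classes gives log(C)
  for (C in c(2, 5, 10)) {
    y <- diag(C)
    p <- matrix(1 / C, C, C)
    expect_equal(classification_loss(loss_batch(cls_target = y, cls_pred = p)),
                 log(C), tolerance = 1e-12)
  }
  expect_error(classification_loss(loss_batch(cls_target = matrix(0.5), cls_pred = matrix(0.5))),
               "one-hot")
})

test_that("box loss is the lambda-weighted sum of squared coordinate errors", {
  t0 <- matrix(c(0.5, 0.5, 0.2, 0.2), 1)
  expect_equal(box_loss(loss_batch(box_target = t0, box_pred = t0)), 0)
  p1 <- t0; p1[1] <- t0[1] + 1
  expect_equal(box_loss(loss_batch(box_target = t0, box_pred = p1)), 1)
  b <- loss_batch(box_target = t0, box_pred = p1, lambda_cor = 2)
  expect_equal(box_loss(b), 2)
})

test_that("segmentation BCE matches hand values and is symmetric at 0.5", {
  expect_lt(segmentation_loss(loss_batch(seg_target = c(1, 0), seg_pred = c(1, 0))), 1e-6)
  expect_equal(segmentation_loss(loss_batch(seg_target = 1, seg_pred = 0.5)),
               -log(0.5), tolerance = 1e-12)
  expect_equal(segmentation_loss(loss_batch(seg_target = 0, seg_pred = 0.5)),
               -log(0.5), tolerance = 1e-12)
})

test_that("total loss composes the three weighted terms", {
  y <- diag(2); p <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  bt <- matrix(c(0.5, 0.5, 0.2, 0.3), 1); bp <- bt + c(0.1, 0, -0.05, 0)
  st <- c(1, 0, 1); sp <- c(0.8, 0.1, 0.6)
  b <- loss_batch(y, p, bt, bp, st, sp, lambda_cor = 1.5, weights = c(1, 1, 1))
  expect_equal(total_loss(b),
               classification_loss(b) + box_loss(b) + segmentation_loss(b),
               tolerance = 1e-12)
  b_cls <- loss_batch(y, p, bt, bp, st, sp, weights = c(1, 0, 0))
  expect_equal(total_loss(b_cls), classification_loss(b_cls))
  zero <- loss_batch(y, ifelse(y == 1, 1 - 1e-7, 1e-7), bt, bt,
                     st, ifelse(st == 1, 1 - 1e-7, 1e-7))
  expect_lt(total_loss(zero), 1e-5)
})

test_that("terms are non-negative and zero only at matching predictions", {
  set.seed(3)
  for (rep in 1:20) {
    y <- diag(3)[sample(3, 4, replace = TRUE), ]
    p <- matrix(runif(12, 0.05, 0.95), 4)
    p <- p / rowSums(p)
    b <- loss_batch(cls_target = y, cls_pred = p,
                    seg_target = rbinom(6, 1, 0.5), seg_pred = runif(6, 0.05, 0.95))
    expect_gte(classification_loss(b), 0)
    expect_gte(segmentation_loss(b), 0)
  }
})

test_that("autograd loss terms have finite, correct gradients (finite differences)", {
  ns <- asNamespace("akbseg")
  set.seed(6)
  z <- ns$ag_param(matrix(rnorm(9), 3, 3))
  tgt <- matrix(rbinom(9, 1, 0.5), 3, 3)
  root <- ns$op_bce_logits(z, tgt)
  ns$ag_backward(root)
  h <- 1e-5
  for (i in sample(9, 4)) {
    v <- z$val[i]
    z$val[i] <- v + h; up <- ns$op_bce_logits(z, tgt)$val
    z$val[i] <- v - h; dn <- ns$op_bce_logits(z, tgt)$val
    z$val[i] <- v
    expect_equal(z$grad[i], (up - dn) / (2 * h), tolerance = 1e-5)
    expect_true(is.finite(z$grad[i]))
  }
})
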