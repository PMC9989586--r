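# Combined BCE + Dice objective and confusion-count metrics.

test_that("BCE closed forms and loop oracle", {
  n <- 12
  expect_equal(bce_loss(rep(1, n), rep(0.5, n)), log(2), tolerance = 1e-9)
  y <- c(1, 0, 1, 1, 0)
  expect_lt(bce_loss(y, y), 1e-6)
  set.seed(51)
  y10 <- (runif(10) > 0.5) * 1
  p10 <- runif(10, 0.01, 0.99)
  s <- 0
  for (i in 1:10) s <- s - (y10[i] * log(p10[i]) + (1 - y10[i]) * log(1 - p10[i]))
  expect_equal(bce_loss(y10, p10), s / 10, tolerance = 1e-9)
  expect_equal(bce_loss(y10, p10, reduce = "sum"), s, tolerance = 1e-9)
  expect_error(bce_loss(y10, p10[1:5]), "shape")
})

test_that("Dice loss limits: perfect, printed-form perfect, empty masks", {
  n <- 64
  ones <- rep(1, n)
  expect_equal(dice_loss(ones, ones), 0, tolerance = 1e-9)
  printed <- loss_config(dice_form = "printed")
  expect_equal(dice_loss(ones, ones, printed), 0.5, tolerance = 1e-3)
  zeros <- rep(0, n)
  expect_equal(dice_loss(zeros, zeros), 0)
  expect_equal(dice_loss(zeros, zeros, printed), 0)
})

test_that("total loss recomposes from its parts and respects the weights", {
  set.seed(52)
  y <- (runif(50) > 0.6) * 1
  p <- runif(50, 0.01, 0.99)
  expect_equal(total_loss(y, p, loss_config(alpha = 1, beta = 0)),
               bce_loss(y, p))
  expect_equal(total_loss(y, p, loss_config(alpha = 0, beta = 1)),
               dice_loss(y, p))
  expect_equal(total_loss(y, p),
               0.5 * bce_loss(y, p) + 0.5 * dice_loss(y, p),
               tolerance = 1e-12)
})

test_that("the differentiable loss node agrees with the pure functions and autodiff", {
  set.seed(53)
  p <- array(runif(6 * 6 * 2, 0.02, 0.98), c(6, 6, 1, 2))
  y <- array((runif(72) > 0.5) * 1, c(6, 6, 1, 2))
  node <- guidedunet:::n_seg_loss(guidedunet:::n_const(p), y)
  manual <- 0.5 * bce_loss(y, p) +
    0.5 * mean(c(dice_loss(y[, , , 1], p[, , , 1]),
                 dice_loss(y[, , , 2], p[, , , 2])))
  expect_equal(node$value, manual, tolerance = 1e-12)
  # finite-difference gradient
  pp <- guidedunet:::gu_param(p)
  fwd <- function() guidedunet:::n_seg_loss(guidedunet:::n_leaf(pp), y)
  guidedunet:::gu_zero_grads(list(pp))
  guidedunet:::gu_backward(fwd())
  eps <- 1e-6
  for (i in sample(length(p), 5)) {
    v0 <- pp$value[i]
    pp$value[i] <- v0 + eps; lp <- fwd()$value
    pp$value[i] <- v0 - eps; lm <- fwd()$value
    pp$value[i] <- v0
    expect_lt(abs((lp - lm) / (2 * eps) - pp$grad[i]), 1e-5)
  }
})

test_that("confusion counts match a per-pixel loop and sum to the pixel count", {
  set.seed(54)
  pred <- matrix(runif(36), 6, 6)
  truth <- matrix((runif(36) > 0.5) * 1, 6, 6)
  cc <- confusion(pred, truth)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:6) for (j in 1:6) {
    pb <- pred[i, j] >= 0.5; tb <- truth[i, j] == 1
    if (pb && tb) tp <- tp + 1L
    if (!pb && !tb) tn <- tn + 1L
    if (pb && !tb) fp <- fp + 1L
    if (!pb && tb) fn <- fn + 1L
  }
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 36L)
  # exact prediction and inverted prediction
  cc2 <- confusion(truth, truth)
  expect_equal(cc2$fp + cc2$fn, 0L)
  cc3 <- confusion(1 - truth, truth)
  expect_equal(cc3$tp + cc3$tn, 0L)
})

test_that("metrics match formulas on an exhaustive small grid and identities hold", {
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) {
    m <- seg_metrics(list(tp = tp, fp = fp, fn = fn))
    if (tp + fp + fn == 0) {
      expect_equal(unlist(m), c(dice = 1, iou = 1, precision = 1, recall = 1))
    } else {
      expect_equal(m$dice, 2 * tp / (2 * tp + fp + fn))
      expect_equal(m$iou, tp / (tp + fp + fn))
      expect_equal(m$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
      expect_equal(m$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
      # F1/Jaccard identity and ordering
      expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
      expect_gte(m$dice, m$iou)
    }
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
  m <- seg_metrics(list(tp = 8, fp = 2, fn = 2))
  expect_equal(unlist(m), c(dice = 0.8, iou = 2 / 3, precision = 0.8,
                            recall = 0.8), tolerance = 1e-12)
})

test_that("metrics are invariant to simultaneous spatial permutation", {
  set.seed(55)
  pred <- runif(40)
  truth <- (runif(40) > 0.5) * 1
  perm <- sample(40)
  m1 <- seg_metrics(confusion(pred, truth))
  m2 <- seg_metrics(confusion(pred[perm], truth[perm]))
  expect_identical(m1, m2)
})
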