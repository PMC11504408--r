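test_that("loss closed forms match hand-derived values", {
  gt <- array(c(1, 0, 1, 0, 1, 1, 0, 0), c(2, 2, 2))

  # BCE at p = 0.5 collapses to ln 2 for any ground truth
  expect_equal(bce_loss(array(0.5, dim(gt)), gt), log(2), tolerance = 1e-12)
  # single-term closed form
  expect_equal(bce_loss(array(0.9, c(2, 2)), array(1, c(2, 2))), -log(0.9),
               tolerance = 1e-12)
  # perfect prediction, clamped
  expect_lt(bce_loss(gt, gt), 1e-6)

  # Dice: 4-pixel square ground truth, prediction overlapping 2 with |pred| = 4
  g8 <- array(0, c(4, 4)); g8[1:2, 1:2] <- 1
  p8 <- array(0, c(4, 4)); p8[2:3, 1:2] <- 1 # overlap rows 2; |pred| = 4
  expect_equal(sum(p8 * g8), 2)
  expect_equal(dice_loss(p8, g8), 0.5)
  expect_equal(dice_loss(g8, g8), 0)
  disj <- array(0, c(4, 4)); disj[3:4, 3:4] <- 1
  expect_equal(dice_loss(disj, g8), 1)

  # Smooth L1 branch agreement at unit error and quadratic branch value
  one <- array(1, c(3, 3)); zero <- array(0, c(3, 3))
  expect_equal(smooth_l1_loss(one, zero, domain = "all"), 0.5)  # d = 1
  expect_equal(smooth_l1_loss(array(0.5, c(3, 3)), zero, domain = "all"), 0.125)
  expect_equal(smooth_l1_loss(zero, zero, domain = "all"), 0)
})

test_that("the hybrid loss is exactly dice + bce + 0.5 * smooth L1", {
  set.seed(30)
  for (rep in 1:5) {
    p <- array(runif(64), c(1, 8, 8))
    g <- array(rbinom(64, 1, 0.3), c(1, 8, 8))
    expect_equal(hybrid_loss(p, g),
                 dice_loss(p, g) + bce_loss(p, g) + 0.5 * smooth_l1_loss(p, g),
                 tolerance = 1e-12)
  }
  # worked component example: dice 0.5, bce ln 2, smooth L1 0.125
  expect_equal(0.5 + log(2) + 0.5 * 0.125, 1.255647, tolerance = 1e-6)
  g8 <- array(0, c(4, 4)); g8[1:2, 1:2] <- 1
  expect_lt(hybrid_loss(g8, g8), 1e-5)
})

test_that("losses reject malformed pairs and non-binary ground truth", {
  p <- array(0.5, c(2, 2))
  expect_error(bce_loss(p, array(0, c(2, 3))), "shape")
  expect_error(dice_loss(p, array(0.5, c(2, 2))), "binary")
})

test_that("losses are invariant to duplicating the batch", {
  set.seed(31)
  p <- array(runif(32), c(1, 1, 4, 8))
  g <- array(rbinom(32, 1, 0.4), c(1, 1, 4, 8))
  p2 <- array(0, c(2, 1, 4, 8)); p2[1, , , ] <- p; p2[2, , , ] <- p
  g2 <- array(0, c(2, 1, 4, 8)); g2[1, , , ] <- g; g2[2, , , ] <- g
  expect_equal(bce_loss(p2, g2), bce_loss(p, g), tolerance = 1e-12)
  expect_equal(dice_loss(p2, g2), dice_loss(p, g), tolerance = 1e-12)
  expect_equal(smooth_l1_loss(p2, g2), smooth_l1_loss(p, g), tolerance = 1e-12)
})

test_that("each loss has a nonzero gradient wherever pred != gt", {
  set.seed(32)
  ns <- asNamespace("mrdbseg")
  p <- array(runif(16, 0.05, 0.95), c(4, 4))
  g <- array(rbinom(16, 1, 0.5), c(4, 4))
  for (lf in list(ns$ag_bce, ns$ag_dice, ns$ag_smooth_l1)) {
    ns$ag_tape_begin()
    pn <- ns$ag_const(p)
    loss <- lf(pn, g)
    ns$ag_backward(loss)
    ns$ag_tape_end()
    grad <- pn$grad
    if (identical(lf, ns$ag_smooth_l1)) {
      # foreground domain: gradient lives on mask pixels
      expect_true(all(abs(grad[g > 0 & p != g]) > 0))
    } else {
      expect_true(all(abs(grad[p != g]) > 0))
    }
  }
  # analytic-vs-numeric check on the hybrid loss
  f <- function(z) hybrid_loss(array(z, dim(p)), g)
  ns$ag_tape_begin()
  pn <- ns$ag_const(p)
  loss <- ns$ag_hybrid(pn, g)
  ns$ag_backward(loss)
  ns$ag_tape_end()
  expect_lt(fd_grad_err(f, p, pn$grad), 1e-5)
})
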