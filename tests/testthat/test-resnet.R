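test_that("basic block reduces to identity when F is zero", {
  set.seed(1)
  w <- resnet_block_init(8, 8, 1L)
  w$conv1$w$value[] <- 0
  w$conv2$w$value[] <- 0
  x <- array(abs(rnorm(1 * 8 * 12 * 12)), c(1, 8, 12, 12)) # nonnegative
  expect_equal(basic_block_forward(x, w), x, tolerance = 1e-10)
})

test_that("basic block shape contracts hold", {
  set.seed(2)
  w <- resnet_block_init(16, 16, 1L)
  x <- array(rnorm(1 * 16 * 32 * 32), c(1, 16, 32, 32))
  expect_identical(dim(basic_block_forward(x, w)), c(1L, 16L, 32L, 32L))
  # stage transition: stride-2 channel-doubling block halves resolution
  wd <- resnet_block_init(16, 32, 2L)
  expect_identical(dim(basic_block_forward(x, wd)), c(1L, 32L, 16L, 16L))
  expect_error(basic_block_forward(x, resnet_block_init(8, 8, 1L)), "channel")
})

test_that("encoder pyramid follows the S/4..S/32 schedule at any width", {
  set.seed(3)
  w <- resnet34_init(1, 8)
  img <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  pyr <- resnet34_encode(img, w)
  expect_s3_class(pyr, "encoder_pyramid")
  expect_equal(pyr$branch_tag, "ResNet")
  sides <- sapply(pyr$stages, function(s) dim(s)[3])
  chans <- sapply(pyr$stages, function(s) dim(s)[2])
  expect_equal(sides, c(16, 8, 4, 2))
  expect_equal(chans, 8 * c(1, 2, 4, 8))
  expect_equal(sapply(w$stages, length), c(3, 4, 6, 3))
  expect_error(resnet34_encode(array(0, c(1, 1, 48, 48)), w), "divisible")
})

test_that("trainable parameter count matches an independent per-layer tally", {
  set.seed(4)
  w <- resnet34_init(1, 64)
  # independent arithmetic: conv kernels (no bias) + batchnorm gamma/beta
  conv_p <- function(cin, cout, k) cin * cout * k * k
  bn_p <- function(c) 2 * c
  tally <- conv_p(1, 64, 7) + bn_p(64)
  stage <- function(cin, cout, nblocks) {
    tot <- 0
    for (b in seq_len(nblocks)) {
      ci <- if (b == 1) cin else cout
      tot <- tot + conv_p(ci, cout, 3) + bn_p(cout) +
        conv_p(cout, cout, 3) + bn_p(cout)
      if (b == 1 && (ci != cout)) tot <- tot + conv_p(ci, cout, 1) + bn_p(cout)
    }
    tot
  }
  tally <- tally + stage(64, 64, 3) + stage(64, 128, 4) +
    stage(128, 256, 6) + stage(256, 512, 3)
  expect_equal(count_params(w), tally)
})

test_that("gradients reach conv1 from a loss on the deepest stage", {
  set.seed(5)
  w <- resnet34_init(1, 4)
  img <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  ns <- asNamespace("mrdbseg")
  ns$ag_tape_begin()
  out <- ns$ag_resnet34(w, ns$ag_const(img), list(training = TRUE))
  loss <- ns$ag_mean(ns$ag_mul(out[[4]], out[[4]]))
  ns$ag_backward(loss)
  ns$ag_tape_end()
  expect_gt(sum(abs(w$conv1$w$grad)), 0)
})
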