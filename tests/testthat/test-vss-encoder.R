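test_that("state-space and residual pyramids are shape-congruent", {
  set.seed(6)
  vw <- vss_encoder_init(1, 8, blocks = 1L, state_dim = 4L)
  rw <- resnet34_init(1, 8)
  img <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  pv <- vss_encode(img, vw)
  pr <- resnet34_encode(img, rw)
  expect_equal(pv$branch_tag, "VSSB")
  for (s in 1:4) {
    expect_identical(dim(pv$stages[[s]]), dim(pr$stages[[s]]))
    expect_true(all(is.finite(pv$stages[[s]])))
  }
  sides <- sapply(pv$stages, function(s) dim(s)[3])
  expect_equal(sides, c(16, 8, 4, 2))
  expect_equal(sapply(pv$stages, function(s) dim(s)[2]), 8 * c(1, 2, 4, 8))
  expect_error(vss_encode(array(0, c(1, 1, 40, 40)), vw), "divisible")
})
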