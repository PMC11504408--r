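test_that("both decoder stage types double the side and halve channels", {
  set.seed(7)
  x <- array(rnorm(1 * 64 * 8 * 8), c(1, 64, 8, 8))
  for (ord in c("left", "right")) {
    w <- decoder_stage_init(64, 32, ord)
    y <- if (ord == "left") left_decoder_stage(x, w) else right_decoder_stage(x, w)
    expect_identical(dim(y), c(1L, 32L, 16L, 16L))
  }
  # four composed stages: 8x8 -> 128x128 (2^4 doubling)
  set.seed(8)
  z <- array(rnorm(1 * 16 * 8 * 8), c(1, 16, 8, 8))
  chans <- c(16, 8, 8, 4, 4)
  for (s in 1:4) {
    w <- decoder_stage_init(chans[s], chans[s + 1], "left")
    z <- left_decoder_stage(z, w)
  }
  expect_identical(dim(z)[3:4], c(128L, 128L))
})

test_that("stage types differ only in operation order", {
  wl <- decoder_stage_init(64, 32, "left")
  wr <- decoder_stage_init(64, 32, "right")
  # left runs its convolutions after upsampling (cout channels); right
  # learns features before upsampling (conv_a still at cin channels)
  expect_equal(dim(wl$conv_a$conv$w$value)[1:2], c(32, 32))
  expect_equal(dim(wr$conv_a$conv$w$value)[1:2], c(64, 64))
  expect_equal(dim(wl$up$w$value)[1:2], c(64, 32))
  expect_equal(dim(wr$up$w$value)[1:2], c(64, 32))
})

test_that("zero input yields zero output in the bias-free configuration", {
  set.seed(9)
  x0 <- array(0, c(2, 16, 4, 4))
  for (ord in c("left", "right")) {
    w <- decoder_stage_init(16, 8, ord)
    y <- if (ord == "left") left_decoder_stage(x0, w) else right_decoder_stage(x0, w)
    expect_equal(max(abs(y)), 0)
  }
})
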