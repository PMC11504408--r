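test_that("cross-skip fusion obeys the addition and concatenation rules", {
  set.seed(20)
  x <- array(rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  zero <- array(0, dim(x))
  add_rule <- cross_skip_rule("add")
  expect_equal(cross_skip_fuse(x, zero, add_rule), x)
  y <- array(rnorm(length(x)), dim(x))
  expect_equal(cross_skip_fuse(x, y, add_rule), cross_skip_fuse(y, x, add_rule))

  cat_rule <- cross_skip_rule("concat", 8, 8)
  out <- cross_skip_fuse(x, y, cat_rule)
  expect_identical(dim(out), dim(y)) # reduced back to decoder channels
  # channel arithmetic before reduction
  ns <- asNamespace("mrdbseg")
  cc <- ns$ag_concat_ch(ns$ag_const(x), ns$ag_const(y))
  expect_identical(dim(cc$value), c(1L, 16L, 6L, 6L))

  expect_error(cross_skip_fuse(x, array(0, c(1, 8, 3, 3)), add_rule), "spatial")
  expect_error(cross_skip_fuse(x, array(0, c(1, 4, 6, 6)), add_rule), "channel")
})

test_that("output fusion averages identical branches and maps zero to 0.5", {
  set.seed(21)
  logit <- array(rnorm(1 * 1 * 8 * 8), c(1, 1, 8, 8))
  fused <- fuse_outputs(logit, logit)
  expect_equal(fused, 1 / (1 + exp(-logit)), tolerance = 1e-12)
  z <- array(0, c(1, 1, 8, 8))
  expect_equal(fuse_outputs(z, z), array(0.5, dim(z)))
  r <- fuse_outputs(logit, -logit)
  expect_true(all(r > 0 & r < 1))
  expect_error(fuse_outputs(logit, z[, , 1:4, 1:4, drop = FALSE]), "mismatch")
})

test_that("mrdb_forward meets its shape, range and determinism contracts", {
  set.seed(22)
  cfg <- mrdb_config(input_side = 64L, base_channels = 8L, state_dim = 4L,
                     blocks_per_vss_stage = 1L)
  model <- mrdb_init(cfg)
  x <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  p1 <- mrdb_forward(x, model)
  expect_identical(dim(p1), c(1L, 1L, 64L, 64L))
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- mrdb_forward(x, model)
  expect_identical(p1, p2) # bit-identical in inference mode
  expect_error(mrdb_forward(array(0, c(1, 1, 32, 32)), model), "input side")
  expect_error(mrdb_forward(array(0, c(1, 2, 64, 64)), model), "channel")
})

test_that("the all-off configuration is a single plain UNet", {
  set.seed(23)
  cfg <- mrdb_config(input_side = 64L, base_channels = 8L, dual_unet = FALSE,
                     csc = FALSE, resnet = FALSE, r_decoder = FALSE, vssb = FALSE)
  model <- mrdb_init(cfg)
  expect_null(model$enc_left)
  expect_null(model$fuse)
  expect_false(is.null(model$enc))
  x <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  p <- mrdb_forward(x, model)
  expect_identical(dim(p), c(1L, 1L, 64L, 64L))
  expect_true(all(p > 0 & p < 1))
})

test_that("loss gradients reach both encoder stems end to end", {
  set.seed(24)
  cfg <- mrdb_config(input_side = 64L, base_channels = 8L, state_dim = 4L,
                     blocks_per_vss_stage = 1L)
  model <- mrdb_init(cfg)
  x <- array(rnorm(2 * 1 * 64 * 64), c(2, 1, 64, 64))
  g <- array(stats::rbinom(2 * 64 * 64, 1, 0.2), c(2, 1, 64, 64))
  ns <- asNamespace("mrdbseg")
  params <- ns$ag_params(unclass(model))
  ns$ag_tape_begin()
  pred <- ns$ag_mrdb(model, ns$ag_const(x), list(training = TRUE))
  loss <- ns$ag_hybrid(pred, g)
  ns$ag_zero_grads(params)
  ns$ag_backward(loss)
  ns$ag_tape_end()
  expect_gt(sum(abs(model$enc_left$stem$w$grad)), 0)
  expect_gt(sum(abs(model$enc_right$conv1$w$grad)), 0)
})

test_that("checkpoints round-trip through disk", {
  set.seed(25)
  cfg <- mrdb_config(input_side = 64L, base_channels = 8L, state_dim = 4L,
                     blocks_per_vss_stage = 1L)
  model <- mrdb_init(cfg)
  x <- array(rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  p_before <- mrdb_forward(x, model)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  expect_identical(mrdb_forward(x, restored), p_before)
  unlink(path)
})
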