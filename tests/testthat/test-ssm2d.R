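test_that("scan_expand produces the four fixed traversals", {
  # [[a,b],[c,d]] with a=1, b=2, c=3, d=4
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, 1, 1] <- 1; x[1, 1, 1, 2] <- 2
  x[1, 1, 2, 1] <- 3; x[1, 1, 2, 2] <- 4
  s <- scan_expand(x)
  expect_equal(as.vector(s$sequences$row_major), c(1, 2, 3, 4))
  expect_equal(as.vector(s$sequences$col_major), c(1, 3, 2, 4))
  expect_equal(as.vector(s$sequences$row_major_rev), c(4, 3, 2, 1))
  expect_equal(as.vector(s$sequences$col_major_rev), c(4, 2, 3, 1))

  # single pixel: every traversal identical
  v <- array(7.5, c(1, 1, 1, 1))
  sv <- scan_expand(v)
  for (sq in sv$sequences) expect_equal(as.vector(sq), 7.5)

  expect_error(scan_expand(array(0, c(1, 1, 0, 2))), "empty")
  expect_error(scan_expand(array(NaN, c(1, 1, 2, 2))), "finite")
})

test_that("every scan path is a permutation of the input pixels", {
  set.seed(3)
  for (rep in 1:10) {
    h <- sample(1:7, 1); w <- sample(1:7, 1)
    x <- array(rnorm(2 * 3 * h * w), c(2, 3, h, w))
    s <- scan_expand(x)
    for (sq in s$sequences) {
      expect_equal(dim(sq), c(2, 3, h * w))
      for (bi in 1:2) for (ci in 1:3)
        expect_equal(sort(sq[bi, ci, ]), sort(as.vector(x[bi, ci, , ])))
    }
  }
})

test_that("scan_merge inverts scan_expand: round trip equals 4x exactly", {
  set.seed(4)
  x <- array(rnorm(2 * 2 * 5 * 3), c(2, 2, 5, 3))
  s <- scan_expand(x)
  expect_identical(scan_merge(s), 4 * x)

  zero <- lapply(1:4, function(i) array(0, c(1, 1, 15)))
  expect_equal(scan_merge(zero, 5, 3), array(0, c(1, 1, 5, 3)))

  # one path zeroed on the 2x2 example -> 3x
  x22 <- array(c(1, 3, 2, 4), c(1, 1, 2, 2))
  s22 <- scan_expand(x22)
  s22$sequences$col_major_rev[] <- 0
  expect_equal(scan_merge(s22), 3 * x22)

  bad <- s
  bad$sequences$row_major <- bad$sequences$row_major[, , 1:7, drop = FALSE]
  expect_error(scan_merge(bad), "length")
})

test_that("selective_scan_s6 obeys feedthrough and geometric-decay closed forms", {
  # Abar = 0 (huge negative A), C = 0, D = 1  ->  pure feedthrough
  p <- ssm_params_init(2, state_dim = 3)
  p$A_log$value[] <- 20 # A = -exp(20), Abar ~ 0
  p$C_W$value[] <- 0; p$C_b$value[] <- 0
  p$D$value[] <- 1
  x <- array(rnorm(1 * 2 * 6), c(1, 2, 6))
  expect_equal(selective_scan_s6(x, p), x, tolerance = 1e-12)

  # state_dim 1, constant Abar = 0.5, Bbar = 1, C = 1, D = 0:
  # impulse input (1,0,0,0) -> geometric decay (1, 0.5, 0.25, 0.125)
  q <- ssm_params_init(1, state_dim = 1)
  q$dt_W$value[] <- 0
  q$dt_b$value[] <- log(expm1(1))          # softplus^-1(1): delta = 1
  q$A_log$value[] <- log(log(2))           # A = -ln 2, exp(delta*A) = 0.5
  q$B_W$value[] <- 0; q$B_b$value[] <- 1   # Bbar = delta * B = 1
  q$C_W$value[] <- 0; q$C_b$value[] <- 1
  q$D$value[] <- 0
  imp <- array(c(1, 0, 0, 0), c(1, 1, 4))
  expect_equal(as.vector(selective_scan_s6(imp, q)), c(1, 0.5, 0.25, 0.125),
               tolerance = 1e-10)

  expect_error(selective_scan_s6(array(0, c(1, 2, 0)), p), ">= 1")
  p_bad <- ssm_params_init(2, 3)
  p_bad$D$value[1] <- NaN
  expect_error(selective_scan_s6(x, p_bad), "finite")
})

test_that("selective_scan_s6 matches the sequential-recurrence oracle", {
  set.seed(10)
  for (rep in 1:20) {
    cc <- sample(1:4, 1); L <- sample(1:16, 1); N <- sample(1:6, 1)
    p <- ssm_params_init(cc, N)
    x <- array(rnorm(2 * cc * L), c(2, cc, L))
    got <- selective_scan_s6(x, p)
    ref <- naive_s6(x, p)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("discretized state transitions are stable for nonnegative steps", {
  set.seed(11)
  p <- ssm_params_init(3, 4)
  A <- -exp(p$A_log$value)
  delta <- matrix(abs(rnorm(50)), 50)
  for (dt in delta) expect_true(all(abs(exp(dt * A)) <= 1))
})

test_that("vssb_forward satisfies its shape, residual and finiteness contracts", {
  set.seed(12)
  w <- vssb_init(8, state_dim = 4)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  y <- vssb_forward(x, w)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))

  w0 <- vssb_init(8, state_dim = 4)
  w0$linear_out$w$value[] <- 0
  w0$linear_out$b$value[] <- 0
  expect_equal(vssb_forward(x, w0), x)

  expect_error(vssb_forward(array(0, c(1, 4, 8, 8)), w), "channel")
})
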