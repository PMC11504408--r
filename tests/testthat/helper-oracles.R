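# Independent oracles and small fixture builders.  These deliberately
# avoid the package's own code paths: naive loops, explicit formulas.

# Sequential evaluation of the selective-scan recurrence, one step at a
# time (the reference for the C++ kernel).
naive_selective_scan <- function(u, delta, A, B, C, D) {
  d <- dim(u)
  y <- array(0, d)
  N <- ncol(A)
  for (bi in seq_len(d[1])) for (ci in seq_len(d[2])) {
    h <- numeric(N)
    for (t in seq_len(d[3])) {
      dt <- delta[bi, ci, t]
      ut <- u[bi, ci, t]
      h <- exp(dt * A[ci, ]) * h + dt * B[bi, , t] * ut
      y[bi, ci, t] <- sum(C[bi, , t] * h) + D[ci] * ut
    }
  }
  y
}

# Full selective_scan_s6 oracle: recompute the input-dependent
# projections with plain matrix algebra, then run the naive recurrence.
naive_s6 <- function(seq, p) {
  d <- dim(seq)
  delta <- array(0, d)
  N <- p$state_dim
  B <- array(0, c(d[1], N, d[3]))
  C <- array(0, c(d[1], N, d[3]))
  sp <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  for (bi in seq_len(d[1])) for (t in seq_len(d[3])) {
    xt <- seq[bi, , t]
    delta[bi, , t] <- sp(p$dt_W$value %*% xt + p$dt_b$value)
    B[bi, , t] <- p$B_W$value %*% xt + p$B_b$value
    C[bi, , t] <- p$C_W$value %*% xt + p$C_b$value
  }
  naive_selective_scan(seq, delta, -exp(p$A_log$value), B, C, p$D$value)
}

# Brute-force HD95: explicit boundary extraction, all-pairs distances,
# manual linear-interpolation percentile.
oracle_hd95 <- function(a, b, k = 95) {
  bound <- function(m) {
    out <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      nb4 <- c(if (i > 1) m[i - 1, j] else FALSE,
               if (i < nrow(m)) m[i + 1, j] else FALSE,
               if (j > 1) m[i, j - 1] else FALSE,
               if (j < ncol(m)) m[i, j + 1] else FALSE)
      if (!all(nb4)) out <- rbind(out, c(i, j))
    }
    out
  }
  pct <- function(v, q) {
    v <- sort(v)
    r <- q * (length(v) - 1) + 1
    lo <- floor(r)
    if (lo >= length(v)) return(v[length(v)])
    v[lo] + (r - lo) * (v[lo + 1] - v[lo])
  }
  pa <- bound(a); pb <- bound(b)
  directed <- function(p1, p2) {
    sapply(seq_len(nrow(p1)), function(i)
      min(sqrt((p1[i, 1] - p2[, 1])^2 + (p1[i, 2] - p2[, 2])^2)))
  }
  max(pct(directed(pa, pb), k / 100), pct(directed(pb, pa), k / 100))
}

# Threshold-sweep PR oracle: recount TP/FP at every distinct threshold.
oracle_pr <- function(scores, gt) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(gt)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    prec[i] <- sum(pos & gt) / sum(pos)
    rec[i] <- sum(pos & gt) / P
  }
  r0 <- c(0, rec)
  p0 <- c(prec[1], prec)
  list(precision = prec, recall = rec, threshold = thr,
       auc = sum(diff(r0) * (p0[-1] + p0[-length(p0)]) / 2))
}

# Random blob mask (thresholded smoothed noise) guaranteed nonempty.
random_blob_mask <- function(side, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(side * side), side, side)
  k <- matrix(1, 5, 5) / 25
  sm <- z
  for (rep in 1:2) {
    padded <- matrix(0, side + 4, side + 4)
    padded[3:(side + 2), 3:(side + 2)] <- sm
    out <- matrix(0, side, side)
    for (di in 0:4) for (dj in 0:4)
      out <- out + padded[(1 + di):(side + di), (1 + dj):(side + dj)] / 25
    sm <- out
  }
  m <- sm > stats::quantile(sm, 0.8)
  if (!any(m)) m[side %/% 2, side %/% 2] <- TRUE
  m
}

# Relative finite-difference check of an analytic gradient.
fd_grad_err <- function(f, x, gx, n = 8, eps = 1e-5, seed = 1) {
  set.seed(seed)
  idx <- sample(length(x), min(n, length(x)))
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  max(abs(num - gx[idx]) / pmax(1e-3, abs(num)))
}

# Tiny on-disk phantom dataset shared across pipeline tests.
tiny_dataset_dir <- local({
  cache <- NULL
  function(n = 6, side = 64L, seed = 11L) {
    if (!is.null(cache) && dir.exists(cache)) return(cache)
    dir <- file.path(tempdir(), sprintf("phantoms_%d_%d_%d", n, side, seed))
    if (!dir.exists(dir))
      write_phantom_dataset(dir, n, phantom_spec(image_side = side, seed = seed))
    cache <<- dir
    dir
  }
})
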