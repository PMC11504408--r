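# Minimal reverse-mode automatic differentiation over base-R arrays.
#
# Nodes are environments holding $value, $grad and a backward closure.
# Forward passes record non-leaf nodes on a package-global tape in
# creation order, which is a valid topological order, so the backward
# sweep simply walks the tape in reverse.  Parameters live off-tape and
# persist across steps; their gradients accumulate through the closures.

.ag <- new.env(parent = emptyenv())
.ag$active <- FALSE

ag_tape_begin <- function() {
  .ag$nodes <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$active <- TRUE
  invisible(NULL)
}

ag_tape_end <- function() {
  .ag$nodes <- NULL
  .ag$n <- 0L
  .ag$active <- FALSE
  invisible(NULL)
}

ag_node <- function(value, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  if (isTRUE(.ag$active) && !is.null(bw)) {
    n <- .ag$n + 1L
    if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
    .ag$nodes[[n]] <- nd
    .ag$n <- n
  }
  nd
}

ag_const <- function(value) ag_node(value)

ag_param <- function(value) {
  nd <- ag_node(value)
  nd$is_param <- TRUE
  nd
}

ag_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(root) {
  stopifnot(isTRUE(.ag$active))
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  if (.ag$n > 0L) for (k in seq(.ag$n, 1L)) {
    nd <- .ag$nodes[[k]]
    if (!is.null(nd$grad)) nd$bw(nd)
  }
  invisible(NULL)
}

# Collect parameter nodes from an arbitrarily nested weight list.
ag_params <- function(tree) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(tree)
  out
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise / scalar ops -------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(nd) {
    ag_accum(a, nd$grad); ag_accum(b, nd$grad)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(nd) {
    ag_accum(a, nd$grad); ag_accum(b, -nd$grad)
  })
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b), function(nd) {
    ag_accum(a, nd$grad * b$value); ag_accum(b, nd$grad * a$value)
  })
}

ag_div <- function(a, b) {
  ag_node(a$value / b$value, list(a, b), function(nd) {
    ag_accum(a, nd$grad / b$value)
    ag_accum(b, -nd$grad * a$value / (b$value^2))
  })
}

ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(nd) ag_accum(a, nd$grad * k))
}

ag_shift <- function(a, k) {
  ag_node(a$value + k, list(a), function(nd) ag_accum(a, nd$grad))
}

ag_relu <- function(a) {
  m <- a$value > 0
  ag_node(a$value * m, list(a), function(nd) ag_accum(a, nd$grad * m))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(nd) ag_accum(a, nd$grad * s * (1 - s)))
}

ag_silu <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(a$value * s, list(a), function(nd) {
    ag_accum(a, nd$grad * s * (1 + a$value * (1 - s)))
  })
}

ag_softplus <- function(a) {
  # numerically stable log(1 + exp(x))
  v <- pmax(a$value, 0) + log1p(exp(-abs(a$value)))
  if (!is.null(dim(a$value))) dim(v) <- dim(a$value)
  s <- 1 / (1 + exp(-a$value))
  ag_node(v, list(a), function(nd) ag_accum(a, nd$grad * s))
}

ag_exp <- function(a) {
  v <- exp(a$value)
  ag_node(v, list(a), function(nd) ag_accum(a, nd$grad * v))
}

ag_neg <- function(a) ag_scale(a, -1)

ag_log <- function(a) {
  ag_node(log(a$value), list(a), function(nd) ag_accum(a, nd$grad / a$value))
}

ag_clamp <- function(a, lo, hi) {
  m <- a$value >= lo & a$value <= hi
  v <- pmin(pmax(a$value, lo), hi)
  if (!is.null(dim(a$value))) dim(v) <- dim(a$value)
  ag_node(v, list(a), function(nd) ag_accum(a, nd$grad * m))
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_node(mean(a$value), list(a), function(nd) {
    g <- array(nd$grad / n, if (is.null(dim(a$value))) n else dim(a$value))
    ag_accum(a, g)
  })
}

ag_sum <- function(a) {
  ag_node(sum(a$value), list(a), function(nd) {
    g <- array(nd$grad, if (is.null(dim(a$value))) length(a$value) else dim(a$value))
    ag_accum(a, g)
  })
}

# Elementwise Smooth L1 (Huber at delta = 1) of a difference array.
ag_smooth_l1_elem <- function(d) {
  v <- d$value
  quad <- abs(v) < 1
  out <- ifelse(quad, 0.5 * v^2, abs(v) - 0.5)
  if (!is.null(dim(v))) dim(out) <- dim(v)
  ag_node(out, list(d), function(nd) {
    ag_accum(d, nd$grad * ifelse(quad, v, sign(v)))
  })
}

# Subset by a flat index vector (used to restrict a loss to mask pixels).
ag_subset <- function(a, idx) {
  ag_node(a$value[idx], list(a), function(nd) {
    g <- array(0, dim(a$value))
    g[idx] <- g[idx] + nd$grad
    ag_accum(a, g)
  })
}

## ---- structural ops ------------------------------------------------------

# (b, c, h, w) -> (b, c, h*w); pure reshape, spatial index is column-major.
ag_flatten_hw <- function(a) {
  d <- dim(a$value)
  v <- a$value
  dim(v) <- c(d[1], d[2], d[3] * d[4])
  ag_node(v, list(a), function(nd) {
    g <- nd$grad
    dim(g) <- d
    ag_accum(a, g)
  })
}

ag_unflatten_hw <- function(a, h, w) {
  d <- dim(a$value)
  v <- a$value
  dim(v) <- c(d[1], d[2], h, w)
  ag_node(v, list(a), function(nd) {
    g <- nd$grad
    dim(g) <- d
    ag_accum(a, g)
  })
}

# Reorder the last (sequence) axis by a permutation.
ag_permute_seq <- function(a, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ag_node(a$value[, , perm, drop = FALSE], list(a), function(nd) {
    ag_accum(a, nd$grad[, , inv, drop = FALSE])
  })
}

ag_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[3] == db[3], da[4] == db[4])
  v <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  v[, seq_len(da[2]), , ] <- a$value
  v[, da[2] + seq_len(db[2]), , ] <- b$value
  ag_node(v, list(a, b), function(nd) {
    ag_accum(a, nd$grad[, seq_len(da[2]), , , drop = FALSE])
    ag_accum(b, nd$grad[, da[2] + seq_len(db[2]), , , drop = FALSE])
  })
}

## ---- heavy kernels -------------------------------------------------------

ag_conv2d <- function(x, w, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x$value)
  y <- .cpp_conv2d_fwd(x$value, w$value, stride, pad, groups)
  kd <- dim(w$value)
  ag_node(y, list(x, w), function(nd) {
    ag_accum(x, .cpp_conv2d_bwd_x(nd$grad, w$value, stride, pad, groups, d[3], d[4]))
    ag_accum(w, .cpp_conv2d_bwd_w(x$value, nd$grad, stride, pad, groups, kd[3], kd[4]))
  })
}

# Transpose convolution == adjoint of a stride-s convolution; weights are
# stored (in_channels, out_channels, kh, kw) so the conv kernels can be
# reused with the roles of the two sides swapped.
ag_conv2dT <- function(x, w, stride = 2L) {
  d <- dim(x$value)
  kd <- dim(w$value)
  oh <- (d[3] - 1L) * stride + kd[3]
  ow <- (d[4] - 1L) * stride + kd[4]
  y <- .cpp_conv2d_bwd_x(x$value, w$value, stride, 0L, 1L, oh, ow)
  ag_node(y, list(x, w), function(nd) {
    ag_accum(x, .cpp_conv2d_fwd(nd$grad, w$value, stride, 0L, 1L))
    ag_accum(w, .cpp_conv2d_bwd_w(nd$grad, x$value, stride, 0L, 1L, kd[3], kd[4]))
  })
}

# Per-output-channel bias on a (b, c, h, w) map.
ag_bias_ch <- function(x, bias) {
  d <- dim(x$value)
  v <- x$value + rep(bias$value, each = d[1])
  ag_node(v, list(x, bias), function(nd) {
    ag_accum(x, nd$grad)
    gb <- apply(nd$grad, 2, sum)
    ag_accum(bias, gb)
  })
}

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x$value)
  r <- .cpp_maxpool_fwd(x$value, k, stride, pad)
  ag_node(r$y, list(x), function(nd) {
    ag_accum(x, .cpp_maxpool_bwd(nd$grad, r$argmax, d[3], d[4]))
  })
}

# Channel linear map on a (b, c, L) sequence: y[b,k,l] = W[k,c] x[b,c,l] + bias[k].
ag_seq_linear <- function(x, W, bias = NULL) {
  d <- dim(x$value)
  b <- d[1]; cc <- d[2]; L <- d[3]
  Wv <- W$value
  xm <- matrix(aperm(x$value, c(2, 1, 3)), cc, b * L)
  ym <- Wv %*% xm
  if (!is.null(bias)) ym <- ym + bias$value
  k <- nrow(Wv)
  y <- aperm(array(ym, c(k, b, L)), c(2, 1, 3))
  parents <- if (is.null(bias)) list(x, W) else list(x, W, bias)
  ag_node(y, parents, function(nd) {
    gm <- matrix(aperm(nd$grad, c(2, 1, 3)), k, b * L)
    gx <- aperm(array(crossprod(Wv, gm), c(cc, b, L)), c(2, 1, 3))
    ag_accum(x, gx)
    ag_accum(W, tcrossprod(gm, xm))
    if (!is.null(bias)) ag_accum(bias, rowSums(gm))
  })
}

ag_selective_scan <- function(u, delta, A, Bm, Cm, D) {
  r <- .cpp_selscan_fwd(u$value, delta$value, A$value, Bm$value, Cm$value, D$value)
  ag_node(r$y, list(u, delta, A, Bm, Cm, D), function(nd) {
    g <- .cpp_selscan_bwd(u$value, delta$value, A$value, Bm$value, Cm$value,
                          D$value, r$h, nd$grad)
    ag_accum(u, g$gu); ag_accum(delta, g$gdelta); ag_accum(A, g$gA)
    ag_accum(Bm, g$gB); ag_accum(Cm, g$gC); ag_accum(D, g$gD)
  })
}

## ---- normalizations ------------------------------------------------------

# Batch normalization over (batch, height, width) per channel.  `state` is an
# environment carrying running moments; training mode uses batch statistics.
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    st <- .cpp_bn_stats(x$value)
    mu <- st$mu
    va <- st$var
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$rm
    va <- state$rv
  }
  istd <- 1 / sqrt(va + eps)
  r <- .cpp_bn_fwd(x$value, gamma$value, beta$value, mu, istd)
  ag_node(r$y, list(x, gamma, beta), function(nd) {
    g <- .cpp_bn_bwd(nd$grad, r$xh, gamma$value, istd, training)
    ag_accum(x, g$gx)
    ag_accum(gamma, g$ggamma)
    ag_accum(beta, g$gbeta)
  })
}

# Layer normalization across channels at every spatial position.
ag_layernorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  r <- .cpp_ln_fwd(x$value, gamma$value, beta$value, eps)
  ag_node(r$y, list(x, gamma, beta), function(nd) {
    g <- .cpp_ln_bwd(nd$grad, r$xh, r$istd, gamma$value)
    ag_accum(x, g$gx)
    ag_accum(gamma, g$ggamma)
    ag_accum(beta, g$gbeta)
  })
}
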