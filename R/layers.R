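# Layer constructors: each returns a plain list of parameter nodes plus
# metadata, consumed by fwd_* helpers that emit autodiff nodes.  All
# random initialization draws from the R RNG, so seeding `set.seed()`
# before model construction makes weights reproducible.

kaiming <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    groups = 1L, bias = FALSE) {
  w <- ag_param(kaiming(c(cout, cin %/% groups, k, k), (cin %/% groups) * k * k))
  list(kind = "conv", w = w,
       b = if (bias) ag_param(numeric(cout)) else NULL,
       stride = as.integer(stride), pad = as.integer(pad), groups = as.integer(groups))
}

fwd_conv <- function(l, x) {
  y <- ag_conv2d(x, l$w, l$stride, l$pad, l$groups)
  if (!is.null(l$b)) y <- ag_bias_ch(y, l$b)
  y
}

nn_convT <- function(cin, cout, k = 2L, stride = 2L, bias = FALSE) {
  w <- ag_param(kaiming(c(cin, cout, k, k), cin * k * k))
  list(kind = "convT", w = w,
       b = if (bias) ag_param(numeric(cout)) else NULL,
       stride = as.integer(stride))
}

fwd_convT <- function(l, x) {
  y <- ag_conv2dT(x, l$w, l$stride)
  if (!is.null(l$b)) y <- ag_bias_ch(y, l$b)
  y
}

nn_bn <- function(c) {
  state <- new.env(parent = emptyenv())
  state$rm <- numeric(c)
  state$rv <- rep(1, c)
  list(kind = "bn", gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       state = state)
}

fwd_bn <- function(l, x, ctx) {
  ag_batchnorm(x, l$gamma, l$beta, l$state, training = isTRUE(ctx$training))
}

nn_ln <- function(c) {
  list(kind = "ln", gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)))
}

fwd_ln <- function(l, x) ag_layernorm_ch(x, l$gamma, l$beta)

# conv -> BN -> ReLU
nn_cbr <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(conv = nn_conv(cin, cout, k, stride, pad), bn = nn_bn(cout))
}

fwd_cbr <- function(l, x, ctx) ag_relu(fwd_bn(l$bn, fwd_conv(l$conv, x), ctx))

# Serialize / restore a weight tree (parameter values + batch-norm state)
# as plain nested lists of numeric arrays.
weights_pack <- function(tree) {
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$is_param)) return(list(.param = x$value))
      if (!is.null(x$rm)) return(list(.bnstate = list(rm = x$rm, rv = x$rv)))
      return(NULL)
    }
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  walk(tree)
}

weights_unpack <- function(tree, packed) {
  walk <- function(x, p) {
    if (is.environment(x)) {
      if (isTRUE(x$is_param)) {
        stopifnot(length(x$value) == length(p$.param))
        v <- p$.param
        if (!is.null(dim(x$value))) dim(v) <- dim(x$value)
        x$value <- v
      } else if (!is.null(x$rm)) {
        x$rm <- p$.bnstate$rm
        x$rv <- p$.bnstate$rv
      }
    } else if (is.list(x)) {
      for (nm in seq_along(x)) if (!is.null(x[[nm]])) walk(x[[nm]], p[[nm]])
    }
    invisible(NULL)
  }
  walk(tree, packed)
  invisible(tree)
}

#' Count trainable parameters in a weight tree
#'
#' @param weights A weight structure created by one of the `*_init()`
#'   constructors (e.g. [resnet34_init()], [mrdb_init()]).
#' @return Integer: total number of trainable scalar parameters.
#' @export
count_params <- function(weights) {
  sum(vapply(ag_params(weights), function(p) length(p$value), numeric(1)))
}

#' Adam optimizer state
#'
#' Creates Adam moment buffers for a parameter list.
#' @noRd
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) array(0, if (is.null(dim(p$value))) length(p$value) else dim(p$value))),
       v = lapply(params, function(p) array(0, if (is.null(dim(p$value))) length(p$value) else dim(p$value))),
       t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    v <- p$value - opt$lr * upd
    if (!is.null(dim(p$value))) dim(v) <- dim(p$value) else v <- as.vector(v)
    p$value <- v
  }
  opt
}
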