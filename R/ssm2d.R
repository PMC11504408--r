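# 2D selective scan (SS2D) and the visual state-space block (VSSB).
#
# SS2D bridges 1D selective state-space recurrences and 2D feature maps:
# the map is unrolled along four directional paths ("scan expand"), each
# sequence runs through an input-dependent linear recurrence (the S6
# block), and the four outputs are inverse-permuted back to the grid and
# summed ("scan merge").

#' Directional scan-path permutations
#'
#' Returns the four traversal orders used by the 2D selective scan:
#' row-major, column-major, and their reversals.  Each permutation maps
#' sequence position `t` to the column-major flat index of the pixel
#' visited at step `t`.
#'
#' @param height,width Spatial dimensions (each >= 1).
#' @return Named list of four integer permutations of `1:(height*width)`.
#' @export
scan_paths <- function(height, width) {
  stopifnot(height >= 1, width >= 1)
  L <- height * width
  row_major <- as.vector(t(matrix(seq_len(L), height, width)))
  col_major <- seq_len(L)
  list(row_major = row_major,
       col_major = col_major,
       row_major_rev = rev(row_major),
       col_major_rev = rev(col_major))
}

check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("expected a rank-4 (batch, channel, height, width) array")
  d <- dim(x)
  if (any(d < 1L)) stop("feature map has an empty dimension")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(d)
}

#' Expand a feature map into four directional sequences
#'
#' @param x Rank-4 array (batch, channel, height, width), finite.
#' @return An object of class `directional_sequences`: a list with
#'   `sequences` (four `(batch, channel, L)` arrays, `L = height*width`),
#'   `path_ids`, `height` and `width`.
#' @examples
#' x <- array(1:4, c(1, 1, 2, 2))
#' s <- scan_expand(x)
#' sapply(s$sequences, as.vector)
#' @export
scan_expand <- function(x) {
  d <- check_feature_map(x)
  paths <- scan_paths(d[3], d[4])
  xf <- x
  dim(xf) <- c(d[1], d[2], d[3] * d[4])
  seqs <- lapply(paths, function(p) xf[, , p, drop = FALSE])
  structure(list(sequences = seqs, path_ids = names(paths),
                 height = d[3], width = d[4]),
            class = "directional_sequences")
}

#' Merge directional sequences back into a feature map
#'
#' Each sequence is inverse-permuted to its 2D layout and the four
#' layouts are summed element-wise.  `scan_merge(scan_expand(x))` equals
#' `4 * x` exactly.
#'
#' @param seqs A `directional_sequences` object, or a plain list of four
#'   `(batch, channel, L)` arrays.
#' @param height,width Spatial size to restore (taken from `seqs` when it
#'   is a `directional_sequences` object).
#' @return Rank-4 array (batch, channel, height, width).
#' @export
scan_merge <- function(seqs, height = NULL, width = NULL) {
  if (inherits(seqs, "directional_sequences")) {
    height <- seqs$height; width <- seqs$width
    seqs <- seqs$sequences
  }
  stopifnot(length(seqs) == 4L, !is.null(height), !is.null(width))
  L <- height * width
  paths <- scan_paths(height, width)
  d <- dim(seqs[[1]])
  out <- array(0, c(d[1], d[2], L))
  for (k in seq_len(4L)) {
    s <- seqs[[k]]
    if (dim(s)[3] != L) stop("sequence length ", dim(s)[3], " != height*width = ", L)
    out[, , paths[[k]]] <- out[, , paths[[k]], drop = FALSE] + s
  }
  dim(out) <- c(d[1], d[2], height, width)
  out
}

#' Initialize selective-scan (S6) parameters
#'
#' The recurrence follows the selective state-space formulation with
#' zero-order-hold discretization: `Abar = exp(delta * A)` with
#' `A = -exp(A_log) < 0`, `Bbar = delta * B`, where the step size `delta`
#' and the projections `B`, `C` are affine functions of the input
#' sequence (so the scan is input-dependent), and `D` is a learned
#' feedthrough.  Negative `A` guarantees `|Abar| <= 1` for any
#' nonnegative step size.
#'
#' @param channels Number of sequence channels.
#' @param state_dim Hidden state size per channel (default 16).
#' @return An object of class `ssm_params` (a list of parameter nodes).
#' @export
ssm_params_init <- function(channels, state_dim = 16L) {
  N <- as.integer(state_dim)
  c <- as.integer(channels)
  A_log <- matrix(rep(log(seq_len(N)), each = c), c, N)
  dt0 <- exp(stats::runif(c, log(1e-3), log(1e-1)))
  structure(list(
    state_dim = N, channels = c,
    A_log = ag_param(A_log),
    D = ag_param(rep(1, c)),
    dt_W = ag_param(matrix(stats::rnorm(c * c, sd = 0.1 / sqrt(c)), c, c)),
    dt_b = ag_param(log(expm1(dt0))),
    B_W = ag_param(matrix(stats::rnorm(N * c, sd = 1 / sqrt(c)), N, c)),
    B_b = ag_param(numeric(N)),
    C_W = ag_param(matrix(stats::rnorm(N * c, sd = 1 / sqrt(c)), N, c)),
    C_b = ag_param(numeric(N))
  ), class = "ssm_params")
}

ag_s6 <- function(x, p) {
  delta <- ag_softplus(ag_seq_linear(x, p$dt_W, p$dt_b))
  Bm <- ag_seq_linear(x, p$B_W, p$B_b)
  Cm <- ag_seq_linear(x, p$C_W, p$C_b)
  A <- ag_neg(ag_exp(p$A_log))
  ag_selective_scan(x, delta, A, Bm, Cm, p$D)
}

#' Selective scan (S6) over a sequence
#'
#' Evaluates the input-dependent linear recurrence
#' `h_t = Abar_t h_{t-1} + Bbar_t x_t`, `y_t = C_t . h_t + D x_t`
#' channel-by-channel, with `Abar_t = exp(delta_t A)` and
#' `Bbar_t = delta_t B_t`; `delta`, `B`, `C` are derived from the input
#' via the affine projections in `params`.
#'
#' @param seq Array `(batch, channels, L)` with `L >= 1`.
#' @param params An `ssm_params` object from [ssm_params_init()].
#' @return Array `(batch, channels, L)`.
#' @export
selective_scan_s6 <- function(seq, params) {
  if (!is.array(seq) || length(dim(seq)) != 3L)
    stop("expected a (batch, channels, L) array")
  if (dim(seq)[3] < 1L) stop("sequence length must be >= 1")
  if (dim(seq)[2] != params$channels) stop("channel count does not match params")
  for (p in ag_params(params))
    if (!all(is.finite(p$value))) stop("non-finite selective-scan parameters")
  ag_s6(ag_const(seq), params)$value
}

#' Initialize visual state-space block weights
#'
#' The block layer-normalizes its input, then processes it through two
#' parallel branches: the main branch applies a linear (1x1) projection
#' to `expansion * channels` features, a depth-wise convolution, SiLU,
#' the four-path 2D selective scan, and a second layer normalization;
#' the gate branch applies a linear projection and SiLU.  The branches
#' are fused by element-wise multiplication, projected back to
#' `channels`, and added to the block input.
#'
#' @param channels Input/output channel count of the block.
#' @param state_dim Selective-scan state size (default 16).
#' @param expansion Inner width multiplier (default 2).
#' @param conv_k Depth-wise convolution kernel size (default 3).
#' @return An object of class `vssb_weights`.
#' @export
vssb_init <- function(channels, state_dim = 16L, expansion = 2L, conv_k = 3L) {
  E <- as.integer(expansion * channels)
  structure(list(
    channels = as.integer(channels), inner = E,
    norm1 = nn_ln(channels),
    linear_in_a = nn_conv(channels, E, 1L, bias = TRUE),
    linear_in_b = nn_conv(channels, E, 1L, bias = TRUE),
    dwconv = nn_conv(E, E, conv_k, groups = E, bias = TRUE),
    ssm = lapply(1:4, function(i) ssm_params_init(E, state_dim)),
    norm2 = nn_ln(E),
    linear_out = nn_conv(E, channels, 1L, bias = TRUE)
  ), class = "vssb_weights")
}

ag_ss2d <- function(w, x) {
  d <- dim(x$value)
  paths <- scan_paths(d[3], d[4])
  xf <- ag_flatten_hw(x)
  acc <- NULL
  for (k in seq_len(4L)) {
    s <- ag_permute_seq(xf, paths[[k]])
    y <- ag_s6(s, w$ssm[[k]])
    inv <- integer(length(paths[[k]]))
    inv[paths[[k]]] <- seq_along(paths[[k]])
    back <- ag_permute_seq(y, inv)
    acc <- if (is.null(acc)) back else ag_add(acc, back)
  }
  ag_unflatten_hw(acc, d[3], d[4])
}

ag_vssb <- function(w, x) {
  xn <- fwd_ln(w$norm1, x)
  a <- fwd_conv(w$linear_in_a, xn)
  a <- fwd_conv(w$dwconv, a)
  a <- ag_silu(a)
  a <- ag_ss2d(w, a)
  a <- fwd_ln(w$norm2, a)
  g <- ag_silu(fwd_conv(w$linear_in_b, xn))
  out <- fwd_conv(w$linear_out, ag_mul(a, g))
  ag_add(out, x)
}

#' Visual state-space block forward pass
#'
#' @param x Rank-4 feature map (batch, channel, height, width).
#' @param w Weights from [vssb_init()]; channel count must match `x`.
#' @return Feature map with the same shape as `x`.
#' @export
vssb_forward <- function(x, w) {
  check_feature_map(x)
  if (dim(x)[2] != w$channels)
    stop("channel mismatch: input has ", dim(x)[2], ", block expects ", w$channels)
  ag_vssb(w, ag_const(x))$value
}
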