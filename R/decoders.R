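# Asymmetric decoder stages.
#
# Both stage types double the spatial side and map cin -> cout channels;
# they differ only in operation order:
#   left  decoder: transpose conv (upsample), then two 3x3 convolutions
#   right decoder: 3x3 convolution, transpose conv, 3x3 convolution
# Upsampling is a learnable 2x2 stride-2 transpose convolution rather
# than fixed interpolation.  Each convolution is followed by batch norm
# and ReLU.

#' Initialize a decoder stage
#'
#' @param cin,cout Input/output channel counts.
#' @param order `"left"` (upsample-conv-conv) or `"right"`
#'   (conv-upsample-conv).
#' @return A `decoder_stage_weights` object.
#' @export
decoder_stage_init <- function(cin, cout, order = c("left", "right")) {
  order <- match.arg(order)
  if (order == "left") {
    w <- list(
      up = nn_convT(cin, cout),
      up_bn = nn_bn(cout),
      conv_a = nn_cbr(cout, cout, 3L),
      conv_b = nn_cbr(cout, cout, 3L)
    )
  } else {
    w <- list(
      conv_a = nn_cbr(cin, cin, 3L),
      up = nn_convT(cin, cout),
      up_bn = nn_bn(cout),
      conv_b = nn_cbr(cout, cout, 3L)
    )
  }
  structure(c(w, list(cin = as.integer(cin), cout = as.integer(cout), order = order)),
            class = "decoder_stage_weights")
}

ag_decoder_stage <- function(w, x, ctx) {
  if (w$order == "left") {
    y <- ag_relu(fwd_bn(w$up_bn, fwd_convT(w$up, x), ctx))
    y <- fwd_cbr(w$conv_a, y, ctx)
    fwd_cbr(w$conv_b, y, ctx)
  } else {
    y <- fwd_cbr(w$conv_a, x, ctx)
    y <- ag_relu(fwd_bn(w$up_bn, fwd_convT(w$up, y), ctx))
    fwd_cbr(w$conv_b, y, ctx)
  }
}

#' Left decoder stage: upsample, then two convolutions
#'
#' @param x Feature map `(batch, cin, s, s)`.
#' @param w Weights from `decoder_stage_init(..., order = "left")`.
#' @param training Batch-norm mode.
#' @return Feature map `(batch, cout, 2s, 2s)`.
#' @export
left_decoder_stage <- function(x, w, training = TRUE) {
  check_feature_map(x)
  stopifnot(w$order == "left")
  ag_decoder_stage(w, ag_const(x), list(training = training))$value
}

#' Right decoder stage: convolution, upsample, convolution
#'
#' Same shape signature as [left_decoder_stage()]; only the operation
#' order differs (initial feature learning happens before upsampling).
#'
#' @inheritParams left_decoder_stage
#' @export
right_decoder_stage <- function(x, w, training = TRUE) {
  check_feature_map(x)
  stopifnot(w$order == "right")
  ag_decoder_stage(w, ag_const(x), list(training = training))$value
}

# Full decoder: four stages from side S/32 up to S/2 with channel
# schedule 8C -> 4C -> 2C -> C -> C, then a head (transpose conv x2 +
# 1x1 conv) restoring side S and mapping to a single-channel logit map.
decoder_init <- function(base, order) {
  widths <- base * c(8L, 4L, 2L, 1L, 1L)
  structure(list(
    base = as.integer(base), order = order, widths = widths,
    stages = lapply(1:4, function(s) decoder_stage_init(widths[s], widths[s + 1L], order)),
    head_up = nn_convT(base, base),
    head_bn = nn_bn(base),
    head_out = nn_conv(base, 1L, 1L, pad = 0L, bias = TRUE)
  ), class = "decoder_weights")
}
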