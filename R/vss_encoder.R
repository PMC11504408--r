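# Left encoder branch: patch-embedding stem plus four visual
# state-space stages, shape-aligned with the ResNet pyramid so the
# cross-skip addition is always valid.
#
# Stem: 4x4 stride-4 convolution (side/4); between stages a 2x2
# stride-2 patch-merging convolution halves resolution and doubles
# channels; each stage stacks `blocks` VSSBs.

#' Initialize the visual state-space encoder branch
#'
#' @param in_channels Image channels.
#' @param base Stage-1 channel width (matches the ResNet branch).
#' @param blocks VSSB count per stage (default 2).
#' @param state_dim Selective-scan state size.
#' @param expansion Inner width multiplier of each VSSB.
#' @return A `vss_encoder_weights` object.
#' @export
vss_encoder_init <- function(in_channels = 1L, base = 64L, blocks = 2L,
                             state_dim = 16L, expansion = 2L) {
  widths <- base * c(1L, 2L, 4L, 8L)
  structure(list(
    in_channels = as.integer(in_channels), base = as.integer(base),
    widths = widths, blocks = as.integer(blocks),
    stem = nn_conv(in_channels, base, 4L, stride = 4L, pad = 0L, bias = TRUE),
    stem_ln = nn_ln(base),
    merge = lapply(1:3, function(s)
      nn_conv(widths[s], widths[s + 1L], 2L, stride = 2L, pad = 0L, bias = TRUE)),
    stages = lapply(1:4, function(s)
      lapply(seq_len(blocks), function(k)
        vssb_init(widths[s], state_dim = state_dim, expansion = expansion)))
  ), class = "vss_encoder_weights")
}

ag_vss_encoder <- function(w, x, ctx) {
  y <- fwd_ln(w$stem_ln, fwd_conv(w$stem, x))
  out <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1L) y <- fwd_conv(w$merge[[s - 1L]], y)
    for (blk in w$stages[[s]]) y <- ag_vssb(blk, y)
    out[[s]] <- y
  }
  out
}

#' Encode an image with the visual state-space branch
#'
#' @param image Rank-4 array (batch, channel, side, side); side must be
#'   divisible by 32.
#' @param w Weights from [vss_encoder_init()].
#' @return An `encoder_pyramid` with `branch_tag = "VSSB"`; stage shapes
#'   equal those of [resnet34_encode()] for the same input.
#' @export
vss_encode <- function(image, w) {
  d <- check_feature_map(image)
  if (d[3] %% 32L != 0L || d[4] %% 32L != 0L)
    stop("input side must be divisible by 32, got ", d[3], "x", d[4])
  if (d[2] != w$in_channels)
    stop("expected ", w$in_channels, "-channel input")
  nodes <- ag_vss_encoder(w, ag_const(image), list(training = FALSE))
  structure(list(stages = lapply(nodes, function(n) n$value),
                 branch_tag = "VSSB"),
            class = "encoder_pyramid")
}

# Plain convolutional encoder producing the same pyramid; used for the
# single-UNet baseline and for ablation rows that disable a branch.
plain_encoder_init <- function(in_channels = 1L, base = 64L) {
  widths <- base * c(1L, 2L, 4L, 8L)
  structure(list(
    in_channels = as.integer(in_channels), base = as.integer(base), widths = widths,
    stem = nn_cbr(in_channels, base, 3L, stride = 2L),
    stages = list(
      list(nn_cbr(base, widths[1], 3L, stride = 2L), nn_cbr(widths[1], widths[1], 3L)),
      list(nn_cbr(widths[1], widths[2], 3L, stride = 2L), nn_cbr(widths[2], widths[2], 3L)),
      list(nn_cbr(widths[2], widths[3], 3L, stride = 2L), nn_cbr(widths[3], widths[3], 3L)),
      list(nn_cbr(widths[3], widths[4], 3L, stride = 2L), nn_cbr(widths[4], widths[4], 3L))
    )
  ), class = "plain_encoder_weights")
}

ag_plain_encoder <- function(w, x, ctx) {
  y <- fwd_cbr(w$stem, x, ctx)
  out <- vector("list", 4L)
  for (s in 1:4) {
    for (l in w$stages[[s]]) y <- fwd_cbr(l, y, ctx)
    out[[s]] <- y
  }
  out
}
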