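# ResNet-34 encoder branch (headless).
#
# Stem: 7x7 stride-2 convolution + 3x3 stride-2 max pool; then four
# stages of basic residual blocks with block counts 3/4/6/3.  The
# classification head (global average pool + fully connected layer) is
# omitted: the four stage outputs form the encoder pyramid.  Batch
# normalization follows every convolution; ReLU is the nonlinearity.

#' Initialize a basic residual block
#'
#' The block computes `y = ReLU(F(x) + shortcut(x))` with
#' `F(x) = BN(W2 * ReLU(BN(W1 * x)))` (two 3x3 convolutions).  When
#' `stride > 1` or the channel count changes, the shortcut is a 1x1
#' strided projection with batch norm; otherwise it is the identity.
#'
#' @param cin,cout Input/output channels.
#' @param stride Stride of the first convolution (2 at stage entry).
#' @return A `resnet_block_weights` object.
#' @export
resnet_block_init <- function(cin, cout, stride = 1L) {
  structure(list(
    cin = as.integer(cin), cout = as.integer(cout), stride = as.integer(stride),
    conv1 = nn_conv(cin, cout, 3L, stride = stride),
    bn1 = nn_bn(cout),
    conv2 = nn_conv(cout, cout, 3L),
    bn2 = nn_bn(cout),
    down = if (stride != 1L || cin != cout)
      list(conv = nn_conv(cin, cout, 1L, stride = stride, pad = 0L), bn = nn_bn(cout))
    else NULL
  ), class = "resnet_block_weights")
}

ag_resnet_block <- function(w, x, ctx) {
  f <- ag_relu(fwd_bn(w$bn1, fwd_conv(w$conv1, x), ctx))
  f <- fwd_bn(w$bn2, fwd_conv(w$conv2, f), ctx)
  sc <- if (is.null(w$down)) x else fwd_bn(w$down$bn, fwd_conv(w$down$conv, x), ctx)
  ag_relu(ag_add(f, sc))
}

#' Basic residual block forward pass
#'
#' @param x Rank-4 feature map whose channel count matches `w$cin`.
#' @param w Weights from [resnet_block_init()].
#' @param training Use batch statistics (TRUE) or running moments.
#' @return Feature map; shape preserved for stride-1 same-channel blocks.
#' @export
basic_block_forward <- function(x, w, training = TRUE) {
  check_feature_map(x)
  if (dim(x)[2] != w$cin)
    stop("channel mismatch: input has ", dim(x)[2], ", block expects ", w$cin)
  ag_resnet_block(w, ag_const(x), list(training = training))$value
}

#' Initialize the headless ResNet-34 trunk
#'
#' @param in_channels Image channels (default 1 for grayscale ultrasound).
#' @param base Channel width of the first stage (64 in the reference
#'   layout; smaller values give reduced-width models for desk-scale runs).
#' @return A `resnet34_weights` object.
#' @export
resnet34_init <- function(in_channels = 1L, base = 64L) {
  blocks_per_stage <- c(3L, 4L, 6L, 3L)
  widths <- base * c(1L, 2L, 4L, 8L)
  stages <- vector("list", 4L)
  cin <- base
  for (s in 1:4) {
    n <- blocks_per_stage[s]
    blocks <- vector("list", n)
    for (k in seq_len(n)) {
      stride <- if (s > 1L && k == 1L) 2L else 1L
      blocks[[k]] <- resnet_block_init(cin, widths[s], stride)
      cin <- widths[s]
    }
    stages[[s]] <- blocks
  }
  structure(list(
    in_channels = as.integer(in_channels), base = as.integer(base),
    blocks_per_stage = blocks_per_stage, widths = widths,
    conv1 = nn_conv(in_channels, base, 7L, stride = 2L, pad = 3L),
    bn1 = nn_bn(base),
    stages = stages
  ), class = "resnet34_weights")
}

ag_resnet34 <- function(w, x, ctx) {
  y <- ag_relu(fwd_bn(w$bn1, fwd_conv(w$conv1, x), ctx))
  y <- ag_maxpool(y, 3L, 2L, 1L)
  out <- vector("list", 4L)
  for (s in 1:4) {
    for (blk in w$stages[[s]]) y <- ag_resnet_block(blk, y, ctx)
    out[[s]] <- y
  }
  out
}

#' Encode an image with the ResNet-34 branch
#'
#' @param image Rank-4 array (batch, channel, side, side); side must be
#'   divisible by 32.
#' @param w Weights from [resnet34_init()].
#' @param training Batch-norm mode.
#' @return An `encoder_pyramid`: list with `stages` (four feature maps at
#'   sides side/4, side/8, side/16, side/32 and widths base*(1,2,4,8))
#'   and `branch_tag = "ResNet"`.
#' @export
resnet34_encode <- function(image, w, training = TRUE) {
  d <- check_feature_map(image)
  if (d[3] %% 32L != 0L || d[4] %% 32L != 0L)
    stop("input side must be divisible by 32, got ", d[3], "x", d[4])
  if (d[2] != w$in_channels)
    stop("expected ", w$in_channels, "-channel input")
  nodes <- ag_resnet34(w, ag_const(image), list(training = training))
  structure(list(stages = lapply(nodes, function(n) n$value),
                 branch_tag = "ResNet"),
            class = "encoder_pyramid")
}
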