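# MRDB assembly: dual encoders, cross-skip connections, dual asymmetric
# decoders, shared bottleneck and output fusion, with ablation switches.
#
# Cross-skip rule: features from the state-space (left) encoder are
# ADDED into the right decoder at the matching resolution; features from
# the convolutional (right) encoder are CONCATENATED into the left
# decoder and reduced back by a 3x3 convolution.  With cross-skip
# disabled each decoder takes plain (same-branch, concatenation) skips.

#' MRDB configuration
#'
#' @param input_side Image side in pixels, divisible by 32 (default 256).
#' @param base_channels Stage-1 width (default 64; use 16 for reduced
#'   desk-scale models).
#' @param in_channels Image channels (default 1, grayscale).
#' @param state_dim Selective-scan state size (default 16).
#' @param blocks_per_vss_stage VSSBs per encoder stage (default 2).
#' @param expansion VSSB inner width multiplier (default 2).
#' @param dual_unet Use the dual encoder-decoder structure; FALSE gives
#'   the single plain-UNet baseline.
#' @param csc Use cross-skip connections (addition/concatenation across
#'   branches); FALSE gives plain same-branch skips.
#' @param resnet Use ResNet-34 as the right encoder; FALSE substitutes a
#'   plain convolutional encoder.
#' @param r_decoder Use the conv-upsample-conv order in the right
#'   decoder; FALSE makes both decoders use the left (upsample-conv-conv)
#'   order.
#' @param vssb Use the visual state-space encoder on the left; FALSE
#'   substitutes a plain convolutional encoder.
#' @param fusion `"conv"` (concatenate the two decoder logit maps and
#'   reduce with a 1x1 convolution initialized to averaging) or
#'   `"average"` (mean of the two sigmoid maps).
#' @param pretrained Reserved flag for externally initialized encoder
#'   weights; the default (FALSE) uses Kaiming-random initialization.
#' @return An `mrdb_config` list.
#' @export
mrdb_config <- function(input_side = 256L, base_channels = 64L, in_channels = 1L,
                        state_dim = 16L, blocks_per_vss_stage = 2L, expansion = 2L,
                        dual_unet = TRUE, csc = TRUE, resnet = TRUE,
                        r_decoder = TRUE, vssb = TRUE,
                        fusion = c("conv", "average"), pretrained = FALSE) {
  input_side <- as.integer(input_side)
  if (input_side %% 32L != 0L) stop("input_side must be divisible by 32")
  structure(list(
    input_side = input_side, base_channels = as.integer(base_channels),
    in_channels = as.integer(in_channels), state_dim = as.integer(state_dim),
    blocks_per_vss_stage = as.integer(blocks_per_vss_stage),
    expansion = as.integer(expansion),
    dual_unet = isTRUE(dual_unet), csc = isTRUE(csc), resnet = isTRUE(resnet),
    r_decoder = isTRUE(r_decoder), vssb = isTRUE(vssb),
    fusion = match.arg(fusion), pretrained = isTRUE(pretrained)
  ), class = "mrdb_config")
}

#' Ablation configurations
#'
#' Returns the six cumulative configurations of the component ablation:
#' single UNet baseline, dual UNet, + cross-skip, + ResNet-34 encoder,
#' + right-decoder order, + visual state-space encoder (full model).
#'
#' @param ... Shared arguments forwarded to [mrdb_config()] (e.g.
#'   `input_side`, `base_channels`).
#' @return Named list of six `mrdb_config` objects.
#' @export
ablation_configs <- function(...) {
  list(
    base = mrdb_config(..., dual_unet = FALSE, csc = FALSE, resnet = FALSE,
                       r_decoder = FALSE, vssb = FALSE),
    dual_unet = mrdb_config(..., dual_unet = TRUE, csc = FALSE, resnet = FALSE,
                            r_decoder = FALSE, vssb = FALSE),
    csc = mrdb_config(..., dual_unet = TRUE, csc = TRUE, resnet = FALSE,
                      r_decoder = FALSE, vssb = FALSE),
    resnet = mrdb_config(..., dual_unet = TRUE, csc = TRUE, resnet = TRUE,
                         r_decoder = FALSE, vssb = FALSE),
    r_decoder = mrdb_config(..., dual_unet = TRUE, csc = TRUE, resnet = TRUE,
                            r_decoder = TRUE, vssb = FALSE),
    full = mrdb_config(..., dual_unet = TRUE, csc = TRUE, resnet = TRUE,
                       r_decoder = TRUE, vssb = TRUE)
  )
}

#' Cross-skip fusion rule
#'
#' @param mode `"add"` (element-wise addition; operands must be
#'   channel-identical) or `"concat"` (channel concatenation followed by
#'   a 3x3 convolution reducing back to the decoder's channel count).
#' @param enc_channels,dec_channels Channel counts of the two operands
#'   (needed to build the reducing convolution for `"concat"`).
#' @return A `cross_skip_rule` object.
#' @export
cross_skip_rule <- function(mode = c("add", "concat"),
                            enc_channels = NULL, dec_channels = NULL) {
  mode <- match.arg(mode)
  red <- NULL
  if (mode == "concat") {
    stopifnot(!is.null(enc_channels), !is.null(dec_channels))
    red <- nn_cbr(enc_channels + dec_channels, dec_channels, 3L)
  }
  structure(list(mode = mode, reduce = red), class = "cross_skip_rule")
}

ag_cross_skip <- function(rule, enc, dec, ctx) {
  de <- dim(enc$value); dd <- dim(dec$value)
  if (de[3] != dd[3] || de[4] != dd[4])
    stop("cross-skip spatial mismatch: ", de[3], "x", de[4], " vs ", dd[3], "x", dd[4])
  if (rule$mode == "add") {
    if (de[2] != dd[2])
      stop("cross-skip addition requires channel-identical operands (",
           de[2], " vs ", dd[2], ")")
    ag_add(enc, dec)
  } else {
    fwd_cbr(rule$reduce, ag_concat_ch(enc, dec), ctx)
  }
}

#' Fuse an encoder feature into a decoder feature
#'
#' @param enc_feat,dec_feat Feature maps of equal spatial size.
#' @param rule A [cross_skip_rule()].
#' @param training Batch-norm mode (used by the concat-reducing conv).
#' @return Fused feature map with `dec_feat`'s channel count.
#' @export
cross_skip_fuse <- function(enc_feat, dec_feat, rule, training = TRUE) {
  check_feature_map(enc_feat); check_feature_map(dec_feat)
  ag_cross_skip(rule, ag_const(enc_feat), ag_const(dec_feat),
                list(training = training))$value
}

#' Fuse the two decoder output maps into one probability map
#'
#' Channel-concatenates the two full-resolution logit maps, applies a
#' 1x1 convolution down to one channel, and a sigmoid.  With the default
#' averaging kernel (weights 0.5/0.5, bias 0) and identical inputs this
#' reproduces the sigmoid of either branch alone.
#'
#' @param left_map,right_map Single-channel logit maps of equal shape.
#' @param w Optional fusion weights (a 1x1 conv layer); defaults to the
#'   averaging kernel.
#' @return Probability map in (0, 1), same shape as the inputs.
#' @export
fuse_outputs <- function(left_map, right_map, w = NULL) {
  check_feature_map(left_map)
  if (!identical(dim(left_map), dim(right_map))) stop("shape mismatch")
  if (is.null(w)) {
    w <- nn_conv(2L, 1L, 1L, pad = 0L, bias = TRUE)
    w$w$value <- array(0.5, c(1, 2, 1, 1))
    w$b$value <- 0
  }
  x <- ag_concat_ch(ag_const(left_map), ag_const(right_map))
  ag_sigmoid(fwd_conv(w, x))$value
}

#' Build an MRDB model
#'
#' @param cfg An [mrdb_config()].
#' @return An `mrdb_model` list holding the configuration and all weight
#'   trees the configuration calls for.
#' @export
mrdb_init <- function(cfg) {
  stopifnot(inherits(cfg, "mrdb_config"))
  C <- cfg$base_channels
  m <- list(config = cfg)
  if (!cfg$dual_unet) {
    m$enc <- plain_encoder_init(cfg$in_channels, C)
    m$dec <- decoder_init(C, "left")
    m$skips <- lapply(c(4L, 2L, 1L), function(mult)
      cross_skip_rule("concat", C * mult, C * mult))
  } else {
    m$enc_left <- if (cfg$vssb)
      vss_encoder_init(cfg$in_channels, C, cfg$blocks_per_vss_stage,
                       cfg$state_dim, cfg$expansion)
    else plain_encoder_init(cfg$in_channels, C)
    m$enc_right <- if (cfg$resnet) resnet34_init(cfg$in_channels, C)
    else plain_encoder_init(cfg$in_channels, C)
    m$bottleneck <- nn_cbr(16L * C, 8L * C, 1L, pad = 0L)
    m$dec_left <- decoder_init(C, "left")
    m$dec_right <- decoder_init(C, if (cfg$r_decoder) "right" else "left")
    # skips fuse at sides S/16, S/8, S/4 (encoder stages 3, 2, 1)
    m$skips_left <- lapply(c(4L, 2L, 1L), function(mult)
      cross_skip_rule("concat", C * mult, C * mult))
    m$skips_right <- if (cfg$csc)
      lapply(c(4L, 2L, 1L), function(mult) cross_skip_rule("add"))
    else lapply(c(4L, 2L, 1L), function(mult)
      cross_skip_rule("concat", C * mult, C * mult))
    if (cfg$fusion == "conv") {
      m$fuse <- nn_conv(2L, 1L, 1L, pad = 0L, bias = TRUE)
      m$fuse$w$value <- array(0.5, c(1, 2, 1, 1))
      m$fuse$b$value <- 0
    }
  }
  structure(m, class = "mrdb_model")
}

ag_decoder_run <- function(dec, skips, enc_stages, bottom, ctx) {
  y <- bottom
  for (s in 1:4) {
    y <- ag_decoder_stage(dec$stages[[s]], y, ctx)
    if (s <= 3L) y <- ag_cross_skip(skips[[s]], enc_stages[[4L - s]], y, ctx)
  }
  y <- ag_relu(fwd_bn(dec$head_bn, fwd_convT(dec$head_up, y), ctx))
  fwd_conv(dec$head_out, y)
}

ag_mrdb <- function(m, x, ctx) {
  cfg <- m$config
  if (!cfg$dual_unet) {
    enc <- ag_plain_encoder(m$enc, x, ctx)
    logits <- ag_decoder_run(m$dec, m$skips, enc, enc[[4L]], ctx)
    return(ag_clamp(ag_sigmoid(logits), 1e-12, 1 - 1e-12))
  }
  encL <- if (cfg$vssb) ag_vss_encoder(m$enc_left, x, ctx)
          else ag_plain_encoder(m$enc_left, x, ctx)
  encR <- if (cfg$resnet) ag_resnet34(m$enc_right, x, ctx)
          else ag_plain_encoder(m$enc_right, x, ctx)
  bottom <- fwd_cbr(m$bottleneck, ag_concat_ch(encL[[4L]], encR[[4L]]), ctx)
  skipL_src <- if (cfg$csc) encR else encL # left decoder concatenates conv features
  skipR_src <- if (cfg$csc) encL else encR # right decoder adds state-space features
  logitL <- ag_decoder_run(m$dec_left, m$skips_left, skipL_src, bottom, ctx)
  logitR <- ag_decoder_run(m$dec_right, m$skips_right, skipR_src, bottom, ctx)
  p <- if (cfg$fusion == "conv") {
    ag_sigmoid(fwd_conv(m$fuse, ag_concat_ch(logitL, logitR)))
  } else {
    ag_scale(ag_add(ag_sigmoid(logitL), ag_sigmoid(logitR)), 0.5)
  }
  # keep probabilities strictly inside (0, 1) even when the sigmoid
  # saturates in double precision
  ag_clamp(p, 1e-12, 1 - 1e-12)
}

#' MRDB forward pass
#'
#' @param image Rank-4 array (batch, channel, side, side) matching the
#'   model's configured `input_side` and `in_channels`.
#' @param model An `mrdb_model` from [mrdb_init()].
#' @param training Batch-norm mode; inference (`FALSE`) uses running
#'   moments and is fully deterministic.
#' @return Single-channel probability map, same spatial size as the
#'   input, values strictly in (0, 1).
#' @export
mrdb_forward <- function(image, model, training = FALSE) {
  d <- check_feature_map(image)
  cfg <- model$config
  if (d[3] != cfg$input_side || d[4] != cfg$input_side)
    stop("input side ", d[3], "x", d[4], " does not match configured ",
         cfg$input_side)
  if (d[2] != cfg$in_channels) stop("expected ", cfg$in_channels, "-channel input")
  ag_mrdb(model, ag_const(image), list(training = training))$value
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive holding the
#' configuration and every parameter value plus batch-norm running
#' moments; [load_checkpoint()] rebuilds the model and restores them.
#'
#' @param model An `mrdb_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               weights = weights_pack(unclass(model))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(mrdb_config, ck$config[setdiff(names(ck$config), character(0))])
  model <- mrdb_init(cfg)
  weights_unpack(unclass(model), ck$weights)
  model
}
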