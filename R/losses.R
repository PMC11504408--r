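# Training losses: binary cross-entropy, soft Dice, Smooth L1, and the
# hybrid loss  L = L_Dice + L_BCE + 0.5 * L_SmoothL1.
#
# `pred` is a probability map (values in [0, 1]); `gt` is strictly
# binary and shape-identical.  The Smooth L1 term constrains the nodule
# region: by default it averages over ground-truth-foreground pixels
# (falling back to all pixels when the mask is empty), mirroring its
# role as a boundary/foreground regression penalty.

check_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("pred and gt must be shape-identical")
  if (!all(gt %in% c(0, 1))) stop("gt must be strictly binary (0/1)")
  invisible(NULL)
}

ag_bce <- function(pred, gt, eps = 1e-7) {
  p <- ag_clamp(pred, eps, 1 - eps)
  g <- gt
  ll <- ag_add(ag_mul(ag_const(g), ag_log(p)),
               ag_mul(ag_const(1 - g), ag_log(ag_shift(ag_neg(p), 1))))
  ag_neg(ag_mean(ll))
}

ag_dice <- function(pred, gt, smooth = 0) {
  inter <- ag_sum(ag_mul(pred, ag_const(gt)))
  tot <- ag_shift(ag_sum(pred), sum(gt))
  if (smooth == 0 && sum(gt) == 0 && sum(pred$value) == 0) return(ag_const(0))
  ag_shift(ag_neg(ag_div(ag_shift(ag_scale(inter, 2), smooth),
                         ag_shift(tot, smooth))), 1)
}

ag_smooth_l1 <- function(pred, gt, domain = c("foreground", "all")) {
  domain <- match.arg(domain)
  idx <- if (domain == "foreground" && sum(gt) > 0) which(gt > 0) else seq_along(gt)
  d <- ag_sub(ag_subset(pred, idx), ag_const(gt[idx]))
  ag_mean(ag_smooth_l1_elem(d))
}

ag_hybrid <- function(pred, gt, smooth = 0, sl1_domain = "foreground") {
  ag_add(ag_add(ag_dice(pred, gt, smooth), ag_bce(pred, gt)),
         ag_scale(ag_smooth_l1(pred, gt, sl1_domain), 0.5))
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood over all pixels,
#' `-(1/N) sum( g log p + (1-g) log(1-p) )`, with predictions clamped to
#' `[eps, 1-eps]`.
#'
#' @param pred Probability array, values in \[0, 1\].
#' @param gt Binary array, shape-identical to `pred`.
#' @param eps Clamping constant (default 1e-7).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(pred, gt, eps = 1e-7) {
  check_pair(pred, gt)
  ag_bce(ag_const(pred), gt, eps)$value
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p*g) + s) / (sum(p) + sum(g) + s)`.  With the default
#' `smooth = 0`, a pair of empty masks returns 0 (perfect agreement) by
#' convention rather than 0/0.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Scalar in \[0, 1\]: 0 at perfect overlap, 1 at total miss.
#' @export
dice_loss <- function(pred, gt, smooth = 0) {
  check_pair(pred, gt)
  ag_dice(ag_const(pred), gt, smooth)$value
}

#' Smooth L1 loss over the nodule region
#'
#' Per-pixel `0.5 d^2` for `d = |p - g| < 1`, else `|d| - 0.5` (the two
#' branches agree at `d = 1`), averaged over ground-truth-foreground
#' pixels (`domain = "foreground"`, falling back to all pixels when the
#' mask is empty) or over all pixels (`domain = "all"`).
#'
#' @inheritParams bce_loss
#' @param domain Pixel set to average over.
#' @return Nonnegative scalar.
#' @export
smooth_l1_loss <- function(pred, gt, domain = c("foreground", "all")) {
  check_pair(pred, gt)
  ag_smooth_l1(ag_const(pred), gt, domain)$value
}

#' Hybrid segmentation loss
#'
#' Exactly `dice_loss + bce_loss + 0.5 * smooth_l1_loss` of the same
#' prediction/ground-truth pair.
#'
#' @inheritParams dice_loss
#' @param sl1_domain Passed to [smooth_l1_loss()].
#' @return Nonnegative scalar.
#' @export
hybrid_loss <- function(pred, gt, smooth = 0, sl1_domain = "foreground") {
  check_pair(pred, gt)
  ag_hybrid(ag_const(pred), gt, smooth, sl1_domain)$value
}
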