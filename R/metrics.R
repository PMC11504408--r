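# Evaluation metrics: Dice similarity coefficient, Jaccard index,
# sensitivity / false-negative rate, 95th-percentile Hausdorff distance
# over boundary pixels, and pooled pixel-level precision-recall curves.

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  if (all(m %in% c(0, 1))) return(m > 0)
  stop("mask must be logical or strictly 0/1")
}

check_masks <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  list(a = as_mask(a), b = as_mask(b))
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b Binary masks (logical or 0/1), equal shape.
#' @return Fraction in \[0, 1\].
#' @export
dsc <- function(a, b) {
  m <- check_masks(a, b)
  denom <- sum(m$a) + sum(m$b)
  if (denom == 0) return(1)
  2 * sum(m$a & m$b) / denom
}

#' Jaccard index
#'
#' `|A n B| / |A u B|`; two empty masks score 1.  Related to the Dice
#' coefficient by `DSC = 2J / (1 + J)`.
#'
#' @inheritParams dsc
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  m <- check_masks(a, b)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

#' Pixel confusion counts
#'
#' @param pred,gt Binary masks (prediction and ground truth).
#' @return A `confusion_counts` list with fields `TP`, `FP`, `FN`, `TN`
#'   summing to the pixel total.
#' @export
confusion_counts <- function(pred, gt) {
  m <- check_masks(pred, gt)
  structure(list(TP = sum(m$a & m$b), FP = sum(m$a & !m$b),
                 FN = sum(!m$a & m$b), TN = sum(!m$a & !m$b)),
            class = "confusion_counts")
}

#' Sensitivity and false-negative rate
#'
#' `sensitivity = TP / (TP + FN)` and `FNR = FN / (TP + FN)`; the two
#' sum to 1 exactly.  When no positive ground-truth pixels exist
#' (`TP + FN = 0`) both are returned as `NA`.
#'
#' @param counts A `confusion_counts` object (or list with `TP`, `FN`).
#' @return Named numeric vector `c(sensitivity =, fnr =)`.
#' @export
sensitivity_fnr <- function(counts) {
  pos <- counts$TP + counts$FN
  if (pos == 0) return(c(sensitivity = NA_real_, fnr = NA_real_))
  sens <- counts$TP / pos
  # the complement form keeps sensitivity + fnr == 1 exact in floating point
  c(sensitivity = sens, fnr = 1 - sens)
}

# Boundary pixels: foreground with at least one background 4-neighbor
# (image border counts as background).
boundary_pixels <- function(m) {
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

directed_boundary_dists <- function(pa, pb) {
  # Euclidean distance from each boundary pixel of A to the nearest of B
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' 95th-percentile Hausdorff distance
#'
#' `max( P95 d(A -> B), P95 d(B -> A) )` where `d(A -> B)` is the set of
#' Euclidean distances (in pixels) from each boundary pixel of `A` to
#' the nearest boundary pixel of `B`; percentiles use the linear
#' interpolation convention (`stats::quantile`, type 7).
#'
#' @inheritParams dsc
#' @param k Percentile in (0, 100\] (default 95; `k = 100` gives the
#'   exact Hausdorff distance).
#' @return Distance in pixels, or `NA` when either mask is empty.
#' @export
hd95 <- function(a, b, k = 95) {
  m <- check_masks(a, b)
  if (sum(m$a) == 0 || sum(m$b) == 0) return(NA_real_)
  pa <- boundary_pixels(m$a)
  pb <- boundary_pixels(m$b)
  dab <- directed_boundary_dists(pa, pb)
  dba <- directed_boundary_dists(pb, pa)
  max(stats::quantile(dab, k / 100, names = FALSE, type = 7),
      stats::quantile(dba, k / 100, names = FALSE, type = 7))
}

#' Pooled pixel-level precision-recall curve
#'
#' Pixels of all images are pooled; precision and recall are evaluated
#' at every distinct score threshold (predict positive when
#' `score >= t`).  The area under the curve is computed by trapezoidal
#' integration over recall, anchored at recall 0 with the precision of
#' the strictest threshold.
#'
#' @param scores Numeric vector/array (or list of them), values in
#'   \[0, 1\].
#' @param gts Binary masks matching `scores` element-wise.
#' @return List with `curve` (data.frame: threshold, precision, recall)
#'   and `pr_auc`.
#' @export
pr_curve <- function(scores, gts) {
  s <- unlist(lapply(if (is.list(scores)) scores else list(scores), as.numeric))
  g <- unlist(lapply(if (is.list(gts)) gts else list(gts),
                     function(m) as.numeric(as_mask(m))))
  if (length(s) != length(g)) stop("scores and ground truth differ in length")
  P <- sum(g)
  if (P == 0) stop("no positive pixels in ground truth")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; g <- g[o]
  ctp <- cumsum(g)
  cfp <- cumsum(1 - g)
  last <- which(diff(s) != 0) # last index of each distinct threshold block
  keep <- c(last, length(s))
  thr <- s[keep]
  prec <- ctp[keep] / (ctp[keep] + cfp[keep])
  rec <- ctp[keep] / P
  r0 <- c(0, rec)
  p0 <- c(prec[1], prec)
  auc <- sum(diff(r0) * (p0[-1] + p0[-length(p0)]) / 2)
  list(curve = data.frame(threshold = thr, precision = prec, recall = rec),
       pr_auc = auc)
}

#' Per-image metric report
#'
#' @param pred Probability map (2D) or binary mask.
#' @param gt Binary ground-truth mask.
#' @param threshold Binarization threshold for probability inputs.
#' @return A `metrics_report` list: `dsc`, `jaccard`, `sensitivity`,
#'   `fnr`, `hd95`.
#' @export
metrics_report <- function(pred, gt, threshold = 0.5) {
  pm <- if (is.logical(pred) || all(pred %in% c(0, 1))) as_mask(pred) else pred >= threshold
  gm <- as_mask(gt)
  cc <- confusion_counts(pm, gm)
  sf <- sensitivity_fnr(cc)
  structure(list(dsc = dsc(pm, gm), jaccard = jaccard(pm, gm),
                 sensitivity = unname(sf["sensitivity"]),
                 fnr = unname(sf["fnr"]),
                 hd95 = hd95(pm, gm)),
            class = "metrics_report")
}

# Deterministic CSV writer: one row per image plus a mean summary row.
# Columns are fixed: image_id, dsc, jaccard, sensitivity, hd95, fnr.
write_metrics_csv <- function(rows, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  lines <- c("image_id,dsc,jaccard,sensitivity,hd95,fnr",
             vapply(rows, function(r)
               paste(r$image_id, fmt(r$dsc), fmt(r$jaccard), fmt(r$sensitivity),
                     fmt(r$hd95), fmt(r$fnr), sep = ","), character(1)))
  mean_of <- function(f) {
    v <- vapply(rows, function(r) r[[f]], numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  lines <- c(lines, paste("mean", fmt(mean_of("dsc")), fmt(mean_of("jaccard")),
                          fmt(mean_of("sensitivity")), fmt(mean_of("hd95")),
                          fmt(mean_of("fnr")), sep = ","))
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
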