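# Grayscale PNG helpers and bilinear/nearest resampling.

#' Read / write 8-bit grayscale PNG
#'
#' `write_gray_png` accepts an integer matrix (0-255) or a numeric
#' matrix in \[0, 1\]; `read_gray_png` returns a numeric matrix in
#' \[0, 1\] (color images are averaged to grayscale).
#'
#' @param x Matrix of pixel values.
#' @param path File path.
#' @return `read_gray_png`: numeric matrix in \[0, 1\].
#' @export
write_gray_png <- function(x, path) {
  v <- if (max(x) > 1.5) x / 255 else x
  png::writePNG(pmin(pmax(v, 0), 1), path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

#' Resample a matrix to a square side
#'
#' @param x Numeric matrix.
#' @param side Target side in pixels.
#' @param method `"bilinear"` (images) or `"nearest"` (masks).
#' @return `side` x `side` numeric matrix.
#' @export
resize_matrix <- function(x, side, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  n1 <- nrow(x); n2 <- ncol(x)
  if (n1 == side && n2 == side) return(x)
  # map target pixel centers onto source pixel centers
  src_r <- (seq_len(side) - 0.5) * n1 / side + 0.5 - 0.5
  src_c <- (seq_len(side) - 0.5) * n2 / side + 0.5 - 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), n1)
    ci <- pmin(pmax(round(src_c), 1), n2)
    return(x[ri, ci, drop = FALSE])
  }
  r0 <- pmin(pmax(floor(src_r), 1), n1)
  r1 <- pmin(r0 + 1, n1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  c0 <- pmin(pmax(floor(src_c), 1), n2)
  c1 <- pmin(c0 + 1, n2)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  a <- x[r0, c0, drop = FALSE] * (1 - fr) + x[r1, c0, drop = FALSE] * fr
  b <- x[r0, c1, drop = FALSE] * (1 - fr) + x[r1, c1, drop = FALSE] * fr
  a * rep(1 - fc, each = side) + b * rep(fc, each = side)
}
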