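# Synthetic ultrasound phantom generator.
#
# Emulates the statistical character of B-mode thyroid images at desk
# scale: a smoothly varying tissue background carrying multiplicative
# Rayleigh speckle, containing 1-3 hypoechoic (darker) elliptical
# nodules with blurred boundaries and a small foreground fraction.
# Ground truth is the unblurred ellipse union.  Not a physical
# simulation (no attenuation, ray model or time-gain compensation).

# Separable Gaussian blur via banded convolution matrices with edge
# renormalization (kernel mass is rescaled where it overhangs the edge).
gaussian_blur_mat <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  Kr <- smooth1(nrow(x))
  Kc <- smooth1(ncol(x))
  Kr %*% x %*% t(Kc)
}

#' Phantom specification
#'
#' @param image_side Image side in pixels (default 256).
#' @param nodule_count_range Integer interval for the nodule count per
#'   image (default 1-3: most clinical images carry one nodule, a
#'   minority two or more).
#' @param nodule_radius_range Ellipse semi-axis range as a fraction of
#'   the image side (default 0.06-0.16).
#' @param contrast Hypoechoic intensity drop of nodules relative to the
#'   surrounding tissue (default 0.45).
#' @param edge_blur_sigma Gaussian blur (pixels) applied to the nodule
#'   edge in the image only, emulating fuzzy boundaries (default 2.5).
#' @param speckle_strength Mixing weight of the multiplicative Rayleigh
#'   speckle field (default 0.35).
#' @param seed RNG seed; identical spec + seed give bit-identical output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_side = 256L, nodule_count_range = c(1L, 3L),
                         nodule_radius_range = c(0.06, 0.16), contrast = 0.45,
                         edge_blur_sigma = 2.5, speckle_strength = 0.35,
                         seed = 1L) {
  stopifnot(image_side >= 16L, nodule_count_range[1] <= nodule_count_range[2],
            nodule_radius_range[1] <= nodule_radius_range[2],
            contrast >= 0, contrast <= 1)
  # reject specs whose worst case cannot keep the foreground under half the image
  if (nodule_count_range[2] * pi * nodule_radius_range[2]^2 >= 0.5)
    stop("nodule radius range too large for the requested count")
  structure(list(image_side = as.integer(image_side),
                 nodule_count_range = as.integer(nodule_count_range),
                 nodule_radius_range = nodule_radius_range,
                 contrast = contrast, edge_blur_sigma = edge_blur_sigma,
                 speckle_strength = speckle_strength, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic ultrasound phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (integer matrix, 8-bit values 0-255),
#'   `mask` (integer matrix with values 0/255) and `ellipses` (the
#'   analytic parameters of the generated nodules).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_side
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  # smooth tissue background around a mid-gray echo level; blurring iid
  # noise with sd sigma shrinks its sd by ~1/(2 sigma sqrt(pi)), so the
  # field is rescaled back to roughly unit variance before weighting
  sig_bg <- n / 16
  field <- gaussian_blur_mat(matrix(stats::rnorm(n * n), n, n), sig_bg) *
    (2 * sig_bg * sqrt(pi))
  bg <- 0.55 + 0.1 * field
  bg <- pmin(pmax(bg, 0.25), 0.85)

  count <- if (spec$nodule_count_range[2] == 0L) 0L else
    sample(spec$nodule_count_range[1]:spec$nodule_count_range[2], 1L)
  xs <- matrix(rep(seq_len(n), n), n, n)        # row coordinate
  ys <- matrix(rep(seq_len(n), each = n), n, n) # column coordinate
  mask <- matrix(FALSE, n, n)
  ellipses <- list()
  for (k in seq_len(count)) {
    a <- stats::runif(1, spec$nodule_radius_range[1], spec$nodule_radius_range[2]) * n
    b <- stats::runif(1, spec$nodule_radius_range[1], spec$nodule_radius_range[2]) * n
    cx <- stats::runif(1, 0.2 * n, 0.8 * n)
    cy <- stats::runif(1, 0.2 * n, 0.8 * n)
    th <- stats::runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- mask | (u^2 + v^2 <= 1)
    ellipses[[k]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
  }

  soft <- gaussian_blur_mat(mask + 0, spec$edge_blur_sigma)
  img <- bg * (1 - spec$contrast * soft)
  # multiplicative Rayleigh speckle with unit mean
  ray <- sqrt(2 / pi) * sqrt(-2 * log(stats::runif(n * n)))
  img <- img * ((1 - spec$speckle_strength) + spec$speckle_strength * matrix(ray, n, n))
  img <- pmin(pmax(img, 0), 1)
  list(image = matrix(as.integer(round(img * 255)), n, n),
       mask = matrix(as.integer(mask) * 255L, n, n),
       ellipses = ellipses)
}

#' Paired augmentation of an image/mask pair
#'
#' Applies a random subset (each with probability 1/2, fixed by `seed`)
#' of: additive Gaussian noise, histogram equalization, gamma remapping,
#' rectangular cutout (at most 10% of the area, zeroed in the image
#' only), and brightness/contrast jitter.  Intensity-only operations
#' leave the mask untouched; no geometric transforms are applied, so the
#' mask is always returned unchanged.
#'
#' @param image Numeric matrix in \[0, 1\] (or 8-bit integers, which are
#'   rescaled).
#' @param mask Binary mask matrix, returned as-is.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param noise_sd_range,gamma_range,cutout_max_frac Magnitude defaults.
#' @return List with augmented `image` (same scale as the input) and
#'   `mask`, plus `applied`, the names of the operations drawn.
#' @export
augment <- function(image, mask, seed, noise_sd_range = c(0.01, 0.05),
                    gamma_range = c(0.7, 1.4), cutout_max_frac = 0.1) {
  eight_bit <- max(image) > 1.5
  img <- if (eight_bit) image / 255 else image
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  use <- stats::runif(5) < 0.5
  names(use) <- c("noise", "hist_eq", "gamma", "cutout", "jitter")
  if (use["noise"]) {
    sd <- stats::runif(1, noise_sd_range[1], noise_sd_range[2])
    img <- img + matrix(stats::rnorm(length(img), sd = sd), nrow(img))
  }
  if (use["hist_eq"]) {
    r <- rank(img, ties.method = "average")
    img <- matrix((r - 1) / (length(img) - 1), nrow(img))
  }
  if (use["gamma"]) {
    img <- pmin(pmax(img, 0), 1)^stats::runif(1, gamma_range[1], gamma_range[2])
  }
  if (use["cutout"]) {
    n1 <- nrow(img); n2 <- ncol(img)
    h <- max(1L, floor(sqrt(cutout_max_frac) * stats::runif(1) * n1))
    w <- max(1L, floor(sqrt(cutout_max_frac) * stats::runif(1) * n2))
    i0 <- sample.int(n1 - h + 1L, 1L)
    j0 <- sample.int(n2 - w + 1L, 1L)
    img[i0:(i0 + h - 1L), j0:(j0 + w - 1L)] <- 0
  }
  if (use["jitter"]) {
    img <- img * stats::runif(1, 0.8, 1.2) + stats::runif(1, -0.1, 0.1)
  }
  img <- pmin(pmax(img, 0), 1)
  if (eight_bit) img <- matrix(as.integer(round(img * 255)), nrow(img))
  list(image = img, mask = mask, applied = names(use)[use])
}

#' Write a phantom dataset to disk
#'
#' Produces the folder layout the training pipeline reads:
#' `images/phantom_###.png`, `masks/phantom_###.png` (8-bit grayscale,
#' masks valued 0/255) plus `manifest.csv` recording per-image seeds and
#' the generating spec.  Image `i` uses seed `spec$seed + i`, so the
#' whole dataset is reproducible from the spec alone.
#'
#' @param dir Output directory (created if missing).
#' @param n Number of image/mask pairs.
#' @param spec Base [phantom_spec()]; its `seed` anchors the dataset.
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dir, n, spec = phantom_spec()) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("phantom_%03d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i
    ph <- generate_phantom(sp)
    write_gray_png(ph$image, file.path(dir, "images", paste0(ids[i], ".png")))
    write_gray_png(ph$mask, file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  man <- data.frame(image_id = ids, seed = spec$seed + seq_len(n),
                    image_side = spec$image_side,
                    contrast = spec$contrast,
                    edge_blur_sigma = spec$edge_blur_sigma,
                    speckle_strength = spec$speckle_strength)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
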