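test_that("phantom generation is deterministic and respects its spec", {
  sp <- phantom_spec(image_side = 64L, seed = 99L)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  expect_true(all(p1$image >= 0 & p1$image <= 255))
  expect_true(all(p1$mask %in% c(0L, 255L)))

  empty <- generate_phantom(phantom_spec(image_side = 64L,
                                         nodule_count_range = c(0L, 0L)))
  expect_equal(sum(empty$mask), 0)

  expect_error(phantom_spec(nodule_radius_range = c(0.3, 0.4),
                            nodule_count_range = c(3L, 3L)), "too large")
})

test_that("rasterized foreground stays near the analytic ellipse area", {
  for (seed in 1:5) {
    sp <- phantom_spec(image_side = 96L, seed = seed)
    p <- generate_phantom(sp)
    analytic <- sum(sapply(p$ellipses, function(e) pi * e$a * e$b))
    raster <- sum(p$mask > 0)
    # raster area is bounded by the analytic union bound and cannot be
    # tiny relative to it unless ellipses overlap or leave the frame
    expect_lte(raster, analytic * 1.15 + 20)
    expect_gt(raster, 0)
    frac <- raster / length(p$mask)
    expect_lt(frac, 0.5)
  }
})

test_that("mean foreground fraction reflects the class imbalance of the domain", {
  fracs <- vapply(1:100, function(s) {
    p <- generate_phantom(phantom_spec(image_side = 64L, seed = 1000L + s))
    mean(p$mask > 0)
  }, numeric(1))
  expect_lt(mean(fracs), 0.15)
  expect_gt(mean(fracs), 0)
})

test_that("augmentation is seed-deterministic and mask-preserving", {
  sp <- phantom_spec(image_side = 64L, seed = 5L)
  p <- generate_phantom(sp)
  a1 <- augment(p$image, p$mask, seed = 77L)
  a2 <- augment(p$image, p$mask, seed = 77L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, p$mask) # intensity-only ops never touch the mask
  # across many seeds the mask never changes
  for (s in 1:20) expect_identical(augment(p$image, p$mask, seed = s)$mask, p$mask)
})

test_that("rectangle dropping zeroes exactly one axis-aligned rectangle", {
  img <- matrix(0.5, 32, 32)
  hit <- FALSE
  for (s in 1:50) {
    out <- augment(img, matrix(0L, 32, 32), seed = s)
    if (!"cutout" %in% out$applied) next
    # histogram equalization can map a lowest-rank pixel to exactly 0 and
    # jitter shifts the cutout zeros; other ops keep the zero set intact
    if (any(c("hist_eq", "jitter") %in% out$applied)) next
    hit <- TRUE
    zero <- which(out$image == 0, arr.ind = TRUE)
    expect_gt(nrow(zero), 0)
    expect_lte(nrow(zero), 0.1 * length(img) + 32)
    # zero set is a full rectangle: rows x cols cross product
    rows <- sort(unique(zero[, 1])); cols <- sort(unique(zero[, 2]))
    expect_equal(nrow(zero), length(rows) * length(cols))
    expect_equal(rows, seq(min(rows), max(rows)))
    expect_equal(cols, seq(min(cols), max(cols)))
  }
  expect_true(hit) # at least one seed exercised a pure cutout
})

test_that("dataset writer produces the documented layout, reproducibly", {
  d1 <- file.path(tempdir(), "phant_a")
  d2 <- file.path(tempdir(), "phant_b")
  unlink(c(d1, d2), recursive = TRUE)
  sp <- phantom_spec(image_side = 48L, seed = 3L)
  write_phantom_dataset(d1, 3, sp)
  write_phantom_dataset(d2, 3, sp)
  expect_identical(sort(list.files(file.path(d1, "images"))),
                   sprintf("phantom_%03d.png", 1:3))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  for (f in list.files(file.path(d1, "images"))) {
    b1 <- readBin(file.path(d1, "images", f), "raw", 1e6)
    b2 <- readBin(file.path(d2, "images", f), "raw", 1e6)
    expect_identical(b1, b2) # bit-identical datasets from the same spec
  }
  unlink(c(d1, d2), recursive = TRUE)
})
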