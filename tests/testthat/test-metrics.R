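test_that("overlap metrics match hand counts and conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE    # |A| = 4
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE    # |B| = 4, overlap 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(jaccard(a, b), 2 / 6)
  expect_equal(dsc(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  d <- matrix(FALSE, 4, 4); d[3:4, 3:4] <- TRUE
  expect_equal(dsc(a, d), 0)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(dsc(empty, empty), 1)
  expect_error(dsc(a, matrix(FALSE, 3, 3)), "mismatch")
})

test_that("DSC = 2J/(1+J) on random mask pairs", {
  set.seed(40)
  for (rep in 1:50) {
    a <- matrix(runif(100) < runif(1, 0.1, 0.9), 10, 10)
    b <- matrix(runif(100) < runif(1, 0.1, 0.9), 10, 10)
    J <- jaccard(a, b)
    expect_equal(dsc(a, b), 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("sensitivity and FNR share a denominator and sum to one", {
  expect_equal(sensitivity_fnr(list(TP = 3, FN = 1)),
               c(sensitivity = 0.75, fnr = 0.25))
  expect_equal(sensitivity_fnr(list(TP = 5, FN = 0)),
               c(sensitivity = 1, fnr = 0))
  expect_equal(sensitivity_fnr(list(TP = 0, FN = 2)),
               c(sensitivity = 0, fnr = 1))
  expect_true(all(is.na(sensitivity_fnr(list(TP = 0, FN = 0)))))
  set.seed(41)
  for (rep in 1:20) {
    pred <- matrix(runif(64) < 0.5, 8, 8)
    gt <- matrix(runif(64) < 0.5, 8, 8)
    cc <- confusion_counts(pred, gt)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 64)
    sf <- sensitivity_fnr(cc)
    if (!any(is.na(sf))) expect_equal(unname(sum(sf)), 1)
  }
})

test_that("hd95 matches simple geometric cases", {
  a <- matrix(FALSE, 12, 12); a[4:6, 4:6] <- TRUE
  expect_equal(hd95(a, a), 0)
  p1 <- matrix(FALSE, 12, 12); p1[3, 3] <- TRUE
  p2 <- matrix(FALSE, 12, 12); p2[8, 3] <- TRUE # 5 pixels apart on one axis
  expect_equal(hd95(p1, p2), 5)
  expect_true(is.na(hd95(a, matrix(FALSE, 12, 12))))
})

test_that("hd95 agrees with the brute-force oracle, is symmetric, and is
           bounded by the exact Hausdorff distance", {
  for (rep in 1:30) {
    side <- 16 + (rep %% 3) * 8 # up to 32x32
    a <- random_blob_mask(side, seed = 100 + rep)
    b <- random_blob_mask(side, seed = 200 + rep)
    got <- hd95(a, b)
    expect_equal(got, oracle_hd95(a, b), tolerance = 1e-9)
    expect_equal(got, hd95(b, a))
    expect_lte(got, hd95(a, b, k = 100) + 1e-12)
  }
})

test_that("pr_curve matches the threshold-sweep oracle and edge cases", {
  set.seed(42)
  g <- matrix(runif(64) < 0.3, 8, 8)
  if (!any(g)) g[1, 1] <- TRUE

  # perfect ranking
  expect_equal(pr_curve(g + 0, g)$pr_auc, 1)

  # constant score map: single-point curve at precision = prevalence
  const <- matrix(0.7, 8, 8)
  expect_equal(pr_curve(const, g)$pr_auc, mean(g), tolerance = 1e-12)

  # random scores vs brute-force sweep (200 pixels)
  s <- matrix(round(runif(200), 2), 10, 20)
  gg <- matrix(runif(200) < 0.25, 10, 20)
  if (!any(gg)) gg[1, 1] <- TRUE
  got <- pr_curve(s, gg)
  ref <- oracle_pr(as.numeric(s), as.logical(gg))
  expect_equal(got$curve$precision, ref$precision, tolerance = 1e-12)
  expect_equal(got$curve$recall, ref$recall, tolerance = 1e-12)
  expect_equal(got$pr_auc, ref$auc, tolerance = 1e-12)

  expect_error(pr_curve(const, matrix(FALSE, 8, 8)), "no positive")
})

test_that("metrics_report assembles the per-image fields consistently", {
  set.seed(43)
  gt <- random_blob_mask(24, seed = 7)
  p <- matrix(runif(24 * 24), 24, 24)
  p[gt] <- p[gt] + 0.5
  r <- metrics_report(p, gt, threshold = 0.5)
  pm <- p >= 0.5
  expect_equal(r$dsc, dsc(pm, gt))
  expect_equal(r$fnr, 1 - r$sensitivity, tolerance = 1e-12)
  expect_equal(r$hd95, hd95(pm, gt))
})
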