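test_that("Gaussian membership is 1 at region means and matches the closed form", {
  # two-valued image: every pixel equals its region mean
  f <- matrix(c(0, 200), 8, 8)
  expect_true(all(gaussianMembership(f, 100) == 1))
  # constant image: both region means equal the constant
  expect_true(all(gaussianMembership(matrix(50, 4, 4), 200) == 1))
  # {0, 100} in one region, mean 50, sigma = 50 -> exp(-0.5)
  f <- matrix(c(0, 100), 4, 4)
  m <- gaussianMembership(f, 150)   # everything below threshold
  expect_equal(unique(as.vector(m)), exp(-0.5), tolerance = 1e-12)
})

test_that("fuzzy divergence matches the per-pixel formula, is symmetric and non-negative", {
  expect_equal(fuzzyDivergence(matrix(1, 1, 1), matrix(0, 1, 1)),
               2 - 2 * exp(-1), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
    expect_equal(fuzzyDivergence(a, b), refDivergence(a, b), tolerance = 1e-10)
    expect_equal(fuzzyDivergence(a, b), fuzzyDivergence(b, a))
    expect_gte(fuzzyDivergence(a, b), 0)
    expect_equal(fuzzyDivergence(a, a), 0)
  }
  expect_error(fuzzyDivergence(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("threshold selection equals an independent brute-force scan", {
  set.seed(21)
  f <- matrix(sample(c(rbinom(150, 255, 0.2), rbinom(106, 255, 0.8))), 16, 16)
  seg <- selectThreshold(f)
  ref <- refThresholdScan(f)
  expect_equal(threshold(seg), ref$t)
  expect_equal(divergence(seg), min(ref$d), tolerance = 1e-9)
  # divergence reported at the optimum matches the scan value there
  expect_equal(divergence(seg), ref$d[threshold(seg)], tolerance = 1e-9)
})

test_that("a bimodal image is split between its modes", {
  f <- matrix(c(rep(50, 128), rep(200, 128)), 16, 16)
  seg <- selectThreshold(f)
  expect_gt(threshold(seg), 50)
  expect_lte(threshold(seg), 200)
  expect_identical(rawMask(seg), f >= threshold(seg))
  expect_identical(rawMask(seg), f == 200)
})

test_that("negating an image yields the complementary raw mask", {
  set.seed(4)
  f <- matrix(sample(c(rbinom(128, 255, 0.25), rbinom(128, 255, 0.75))), 16, 16)
  tPos <- refThresholdScan(f)$t
  tNeg <- refThresholdScan(255 - f)$t
  mPos <- f >= tPos
  mNeg <- (255 - f) >= tNeg
  # complementary up to pixels tied at the thresholds
  ties <- f == tPos | (255 - f) == tNeg
  expect_true(all((mPos != mNeg)[!ties]))
})

test_that("constant channels are rejected as degenerate", {
  expect_error(selectThreshold(matrix(128, 16, 16)), "degenerate")
})

test_that("mask refinement fills holes, drops specks and keeps one component", {
  m <- matrix(FALSE, 64, 64)
  rows <- matrix(seq_len(64), 64, 64); cols <- t(rows)
  disk <- (rows - 32)^2 + (cols - 32)^2 <= 15^2
  m[disk] <- TRUE
  m[32, 32] <- FALSE              # 1-pixel hole
  m[5, 5] <- m[5, 6] <- TRUE      # distant speck
  ref <- refineMask(m, radius = 1)
  expect_true(ref[32, 32])
  expect_false(ref[5, 5])
  expect_equal(max(EBImage::bwlabel(ref * 1)), 1)
  # near-idempotence on a smooth disk: boundary changes only
  again <- refineMask(ref, radius = 1)
  expect_gt(diceCoefficient(again, ref), 0.98)
  expect_error(refineMask(matrix(FALSE, 8, 8)), "empty")
})

test_that("cropWound restricts statistics to masked pixels", {
  gw <- tinyWound()
  full <- matrix(TRUE, 64, 64)
  cw <- cropWound(gw$image, full)
  expect_equal(pixels(cw$image), pixels(gw$image))

  cw <- cropWound(gw$image, gw$woundMask)
  expect_equal(sum(cw$mask), sum(gw$woundMask))
  expect_lte(nrow(cw$mask), 64)
  expect_error(cropWound(gw$image, matrix(FALSE, 64, 64)), "empty")
})

test_that("segmentation recovers a synthetic wound of known geometry", {
  gw <- tinyWound()
  seg <- segmentWound(gw$image)
  target <- gw$woundMask & !gw$tissueMasks$necrotic
  expect_gt(diceCoefficient(refinedMask(seg), gw$woundMask), 0.85)
  # the chromatic (granulation + slough) part is recovered almost exactly
  expect_gt(diceCoefficient(refinedMask(seg) & target, target), 0.9)
  # masked area close to ground-truth blob area
  expect_lt(abs(sum(refinedMask(seg)) - sum(gw$woundMask)) / sum(gw$woundMask),
            0.25)
})

test_that("two-class saturation images with separated modes segment with Dice >= 0.9", {
  set.seed(31)
  for (rep in 1:3) {
    truth <- matrix(FALSE, 48, 48)
    truth[12:36, 10:38] <- TRUE
    f <- matrix(40, 48, 48) + matrix(rnorm(48 * 48, 0, 4), 48)
    f[truth] <- 160 + rnorm(sum(truth), 0, 4)
    # <= 5% impulse noise
    imp <- sample(48 * 48, round(0.04 * 48 * 48))
    f[imp] <- sample(c(0, 255), length(imp), TRUE)
    f <- round(pmin(pmax(f, 0), 255))
    f <- refMedianChannel(f, 3)
    seg <- selectThreshold(f)
    expect_gte(diceCoefficient(refinedMask(seg), truth), 0.9)
  }
})
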