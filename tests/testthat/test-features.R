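test_that("color moments match hand-evaluated population forms", {
  m <- colorMoments(c(1, 2, 3, 4))
  expect_equal(m[["mean"]], 2.5)
  expect_equal(m[["variance"]], 1.25)
  expect_equal(m[["std"]], sqrt(1.25))
  expect_equal(m[["skewness"]], 0)
  expect_equal(m[["kurtosis"]], 1.64)
  const <- colorMoments(c(7, 7, 7))
  expect_equal(unname(const[c("std", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_error(colorMoments(numeric(0)), "empty")
  # invariance to pixel permutation
  set.seed(1); v <- runif(100, 0, 255)
  expect_equal(colorMoments(v), colorMoments(sample(v)))
})

test_that("Shannon entropy over 256 bins hits the closed forms", {
  expect_equal(shannonEntropy(rep(42, 50)), 0)
  expect_equal(shannonEntropy(rep(c(0, 255), 25)), 1)
  expect_equal(shannonEntropy(rep(c(0, 80, 160, 240), 10)), 2)
  # binning respects the declared range, not the data range
  expect_equal(shannonEntropy(rep(c(0.1, 0.9), 10), range = c(0, 1)), 1)
})

test_that("local contrast matches hand evaluation and conventions", {
  expect_equal(localContrast(c(2, 2, 8, 8), "mean"), 0.6)
  expect_equal(localContrast(c(1, 3, 5, 7), "mean"), 0.5)
  expect_equal(localContrast(c(5, 5, 5), "mean"), 0)    # empty lower side
  expect_equal(localContrast(c(2, 2, 8, 8), "median"), 0.6)
  expect_equal(localContrast(c(2, 2, 8, 8, 8), "mode"), 0.6)
  # modal bin is the smallest on ties, emptying the lower side
  expect_equal(localContrast(c(2, 2, 8, 8), "mode"), 0)
  expect_error(localContrast(5), "at least 2")
})

test_that("rotation-invariant LBP equals brute force over all rotations", {
  expect_equal(lbpCode(c(6, 2, 7, 9, 1, 3, 8, 4), 5), 77)
  expect_equal(lbpRICode(c(6, 2, 7, 9, 1, 3, 8, 4), 5), 53)
  expect_equal(lbpRICode(rep(9, 8), 9), 255)   # flat patch: all bits set
  set.seed(13)
  for (P in c(8, 16, 24)) {
    for (i in 1:20) {
      nb <- sample(0:255, P, TRUE); ct <- sample(0:255, 1)
      expect_equal(lbpRICode(nb, ct), refLbpRi(nb, ct),
                   info = sprintf("P=%d rep=%d", P, i))
      # invariance under circular rotation of the neighbor list
      k <- sample(P, 1)
      rot <- nb[((seq_len(P) - 1 + k) %% P) + 1]
      expect_equal(lbpRICode(rot, ct), lbpRICode(nb, ct))
    }
  }
})

test_that("neighborhood variance matches the closed form", {
  # 8 sampled neighbors alternating 0/255: mu = 127.5, VAR = 127.5^2
  expect_equal(neighborVariance(rep(c(0, 255), 4)), 16256.25)
  expect_equal(neighborVariance(rep(9, 16)), 0)
})

test_that("LBP/VAR region means agree with a per-pixel sampling oracle", {
  set.seed(23)
  q <- matrix(sample(0:255, 14 * 14, TRUE), 14, 14)
  mask <- matrix(TRUE, 14, 14)
  for (R in 1:2) {
    P <- 8 * R
    codes <- vars <- c()
    for (i in seq_len(14)) for (j in seq_len(14)) {
      lo <- R + 1; hiR <- 14 - R
      if (i < lo || i > hiR || j < lo || j > hiR) next   # full support only
      nb <- refNeighbors(q, i, j, R)
      codes <- c(codes, refLbpRi(nb, q[i, j]))
      vars <- c(vars, neighborVariance(nb))
    }
    f <- lbpVarFeatures(q, mask, R = R)
    expect_equal(f[["lbp"]], mean(codes), tolerance = 1e-9,
                 info = sprintf("R=%d", R))
    expect_equal(f[["var"]], mean(vars), tolerance = 1e-9,
                 info = sprintf("R=%d", R))
  }
})

test_that("flat and textured regions order LBP/VAR features sensibly", {
  mask <- matrix(TRUE, 16, 16)
  flat <- matrix(100, 16, 16)
  f <- lbpVarFeatures(flat, mask, R = 1)
  expect_equal(f[["var"]], 0)
  expect_equal(f[["lbp"]], 255)    # all-ones code on a constant patch
  checker <- 255 * ((row(flat) + col(flat)) %% 2)
  expect_gt(lbpVarFeatures(checker, mask, R = 1)[["var"]], 0)
  # no pixel with full support -> zeros with warning
  tiny <- matrix(FALSE, 16, 16); tiny[1, seq(1, 15, 2)] <- TRUE
  expect_warning(z <- lbpVarFeatures(checker, tiny, R = 3), "neighborhood")
  expect_equal(unname(z), c(0, 0))
})

test_that("the descriptor has 675 finite entries in manifest order", {
  expect_length(featureManifest(), 675)
  gw <- tinyWound()
  v <- extractFeatures(gw$image, gw$regions[[1]])
  expect_length(v, 675)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), featureManifest())
})

test_that("a constant-color region zeroes all spread features", {
  px <- array(0, c(32, 32, 3))
  px[, , 1] <- 180; px[, , 2] <- 40; px[, , 3] <- 50
  img <- rgbImage(px, "flat")
  mask <- matrix(FALSE, 32, 32); mask[8:24, 8:24] <- TRUE
  v <- extractFeatures(img, tissueRegion(mask, "granulation", "flat"))
  idx <- grep("\\.(std|variance|entropy|var_r[123])$", names(v))
  expect_true(all(v[idx] == 0))
  expect_true(all(is.finite(v)))
})

test_that("texture features are invariant to 90-degree rotation within 2%", {
  gw <- tinyWound(seed = 17)
  reg <- gw$regions[[1]]
  v1 <- extractFeatures(gw$image, reg)
  rotPx <- pixels(gw$image)
  rot <- array(0, c(dim(rotPx)[2], dim(rotPx)[1], 3))
  for (k in 1:3) rot[, , k] <- t(rotPx[nrow(rotPx):1, , k])
  rotMask <- t(regionMask(reg)[nrow(regionMask(reg)):1, ])
  v2 <- extractFeatures(rgbImage(rot, "rot"),
                        tissueRegion(rotMask, regionLabel(reg), "rot"))
  tex <- grep("\\.(lbp_r[123]|var_r[123])$", names(v1), value = TRUE)
  big <- v1[tex] != 0
  relerr <- abs(v2[tex][big] - v1[tex][big]) / abs(v1[tex][big])
  expect_lt(max(relerr), 0.02)
  # color moments are exactly invariant to any in-mask permutation
  mom <- grep("\\.(mean|std|variance|skewness|kurtosis)$", names(v1))
  expect_equal(v1[mom], v2[mom], tolerance = 1e-10)
})

test_that("feature tables round-trip through CSV bit-identically", {
  ft <- benchFeatures()[1:3, ]
  tf <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, tf)
  back <- readFeatureTable(tf)
  expect_identical(names(back), names(ft))
  expect_equal(as.matrix(back[, -(1:3)]), as.matrix(ft[, -(1:3)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$label, ft$label)
  expect_equal(ncol(back), 678)
})
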