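# Independent reference implementations used as oracles. These are
# deliberately naive (per-pixel loops, direct formula transcription) and
# share no code with the package internals.

# replicated-border median filter, one channel
refMedianChannel <- function(m, window) {
  r <- (window - 1) / 2
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- pmin(pmax((i - r):(i + r), 1), h)
    jj <- pmin(pmax((j - r):(j + r), 1), w)
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# per-pixel exponential fuzzy divergence between two membership maps
refDivergence <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) {
    mA <- a[i]; mB <- b[i]
    s <- s + 2 - (1 - mA + mB) * exp(mA - mB) - (1 - mB + mA) * exp(mB - mA)
  }
  s
}

# Gaussian membership of a thresholded gray image, per-pixel
refMembership <- function(f, t) {
  sigma <- max((max(f) - min(f)) / 2, 1)
  obj <- f >= t
  muO <- if (any(obj)) mean(f[obj]) else 0
  muB <- if (any(!obj)) mean(f[!obj]) else 0
  out <- f * 0
  for (i in seq_along(f))
    out[i] <- exp(-(f[i] - ifelse(obj[i], muO, muB))^2 / (2 * sigma^2))
  matrix(out, nrow(f))
}

# exhaustive threshold scan against the ideal (all-ones) image
refThresholdScan <- function(f) {
  ones <- matrix(1, nrow(f), ncol(f))
  d <- sapply(1:255, function(t) refDivergence(refMembership(f, t), ones))
  list(t = which.min(d), d = d)
}

# brute-force rotation-invariant LBP: recompute the code for every
# circular rotation of the neighbor list and take the minimum
refLbpRi <- function(neighbors, center) {
  P <- length(neighbors)
  codes <- sapply(0:(P - 1), function(k) {
    nb <- neighbors[((seq_len(P) - 1 + k) %% P) + 1]
    sum(as.numeric(nb >= center) * 2^(seq_len(P) - 1))
  })
  min(codes)
}

# per-pixel circular neighbor sampling (bilinear), independent of the
# package's vectorized shifted-matrix implementation
refNeighbors <- function(q, i, j, R) {
  P <- 8 * R
  ang <- 2 * pi * (0:(P - 1)) / P
  sapply(seq_len(P), function(p) {
    y <- round(i - R * sin(ang[p]), 8)
    x <- round(j + R * cos(ang[p]), 8)
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    v <- 0
    for (dy in 0:1) for (dx in 0:1) {
      wgt <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
      if (wgt > 1e-9) v <- v + wgt * q[y0 + dy, x0 + dx]
    }
    v
  })
}

# inverse transforms for round-trip checks
refHsv2rgb <- function(h, s, v) {
  c0 <- v * s
  x <- c0 * (1 - abs((h / 60) %% 2 - 1))
  m <- v - c0
  k <- floor(h / 60) %% 6
  rgb1 <- switch(as.character(k),
    "0" = c(c0, x, 0), "1" = c(x, c0, 0), "2" = c(0, c0, x),
    "3" = c(0, x, c0), "4" = c(x, 0, c0), "5" = c(c0, 0, x))
  (rgb1 + m) * 255
}

refYcbcr2rgb <- function(y, cb, cr) {
  yy <- (y - 16) / 219
  pb <- (cb - 128) / 224
  pr <- (cr - 128) / 224
  r <- yy + 1.402 * pr
  b <- yy + 1.772 * pb
  g <- (yy - 0.299 * r - 0.114 * b) / 0.587
  c(r, g, b) * 255
}

# shared synthetic benchmark (built once per test run; feature tables are
# the slow part so every file reuses the same suite)
.benchCache <- new.env(parent = emptyenv())

benchSuite <- function() {
  if (is.null(.benchCache$suite))
    .benchCache$suite <- makeBenchmark(10, seed = 7)
  .benchCache$suite
}

benchFeatures <- function() {
  if (is.null(.benchCache$features)) {
    suite <- benchSuite()
    .benchCache$features <- do.call(rbind, lapply(suite, function(b)
      extractFeatureTable(medianFilterRGB(b$image), b$regions)))
  }
  .benchCache$features
}

# tiny wound image for fast single-image tests
tinyWound <- function(seed = 5) {
  generateWound(woundSpec(width = 64, height = 64, axes = c(20, 14),
                          seed = seed))
}
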