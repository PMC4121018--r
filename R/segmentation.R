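#' @include AllClasses.R
NULL

## Per-pixel divergence summand against the ideal (membership-1) image:
## d(m) = 2 - (2 - m) e^(m-1) - m e^(1-m); d(1) = 0, decreasing in m.
.divToIdeal <- function(m) 2 - (2 - m) * exp(m - 1) - m * exp(1 - m)

#' Gaussian membership map for a candidate threshold
#'
#' Pixels at or above the threshold form the object region, the rest the
#' background. Each pixel's membership is its Gaussian closeness to its
#' own region's mean gray value,
#' \code{exp(-(f - mu_region)^2 / (2 sigma^2))}, with a common spread
#' \code{sigma = (max - min)/2} of the channel's dynamic range, floored at
#' 1. A pixel exactly at its region mean has membership 1; a constant
#' image therefore has membership 1 everywhere.
#'
#' @param channel a \linkS4class{ChannelImage} with values in \code{[0, 255]}
#'   (quantized to integers internally), or a numeric matrix.
#' @param threshold gray level in \code{[1, 255]}.
#' @return numeric matrix of memberships in \code{[0, 1]}.
#' @export
gaussianMembership <- function(channel, threshold) {
  f <- if (is(channel, "ChannelImage")) round(pixels(channel)) else round(channel)
  if (threshold < 1 || threshold > 255) stop("'threshold' must be in [1, 255]")
  sigma <- max((max(f) - min(f)) / 2, 1)
  obj <- f >= threshold
  mu <- f * 0
  if (any(obj)) mu[obj] <- mean(f[obj])
  if (any(!obj)) mu[!obj] <- mean(f[!obj])
  exp(-(f - mu)^2 / (2 * sigma^2))
}

#' Total fuzzy divergence between two membership maps
#'
#' The exponential discrimination measure between two fuzzy images,
#' summed over all pixels:
#' \deqn{D = \sum_{ij} 2 - (1 - \mu_A + \mu_B) e^{\mu_A - \mu_B}
#'                       - (1 - \mu_B + \mu_A) e^{\mu_B - \mu_A}.}
#' It is symmetric, non-negative, and zero iff the maps are identical.
#'
#' @param a,b numeric matrices of memberships in \code{[0, 1]}, same shape.
#' @return a non-negative scalar.
#' @export
fuzzyDivergence <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("membership maps must have identical shape")
  d <- a - b
  sum(2 - (1 - d) * exp(d) - (1 + d) * exp(-d))
}

#' Select a segmentation threshold by fuzzy-divergence minimization
#'
#' Scans every candidate gray level t in 1..255, computes the Gaussian
#' membership map of the thresholded image and its fuzzy divergence from
#' the ideally segmented image (membership 1 everywhere), and returns the
#' t minimizing the divergence (ties broken toward the smallest t). The
#' scan is exhaustive; gray-level histograms only accelerate the
#' arithmetic. The raw mask is \code{channel >= t}: on a saturation plane
#' the wound is the high-saturation side.
#'
#' @param channel a \linkS4class{ChannelImage} in \code{[0, 255]} (e.g.
#'   from \code{\link{sChannel}}), or a numeric matrix; values are
#'   quantized to integers for the search.
#' @param radius structuring-element radius passed to
#'   \code{\link{refineMask}} (\code{NULL} = size-scaled default).
#' @return a \linkS4class{SegmentationResult}.
#' @export
selectThreshold <- function(channel, radius = NULL) {
  f <- if (is(channel, "ChannelImage")) round(pixels(channel)) else round(channel)
  lo <- min(f); hi <- max(f)
  if (lo == hi) stop("degenerate image: constant channel has no threshold")
  sigma <- max((hi - lo) / 2, 1)
  cnt <- tabulate(as.vector(f) + 1L, nbins = 256L)   # counts of levels 0..255
  lev <- 0:255
  csum <- cumsum(cnt); cwsum <- cumsum(cnt * lev)
  n <- csum[256]; wsum <- cwsum[256]

  best <- Inf; bestT <- NA_integer_
  dvals <- rep(NA_real_, 255)
  for (t in 1:255) {
    nB <- csum[t]; nO <- n - nB                      # background: levels < t
    D <- 0
    if (nB > 0) {
      muB <- cwsum[t] / nB
      mB <- exp(-(lev[1:t] - muB)^2 / (2 * sigma^2))
      D <- D + sum(cnt[1:t] * .divToIdeal(mB))
    }
    if (nO > 0) {
      muO <- (wsum - cwsum[t]) / nO
      mO <- exp(-(lev[(t + 1):256] - muO)^2 / (2 * sigma^2))
      D <- D + sum(cnt[(t + 1):256] * .divToIdeal(mO))
    }
    dvals[t] <- D
    if (D < best) { best <- D; bestT <- t }
  }
  raw <- f >= bestT
  new("SegmentationResult", threshold = as.numeric(bestT), divergence = best,
      rawMask = raw, refinedMask = refineMask(raw, radius = radius))
}

#' Morphological refinement of a raw wound mask
#'
#' Closing then opening with a disk structuring element, hole filling,
#' and retention of the largest 8-connected component, producing a single
#' compact wound region. The disk radius scales with image size as
#' \code{max(1, round(3 * min(h, w) / 512))}.
#'
#' @param raw logical matrix (non-empty).
#' @param radius disk radius; default scales with image size.
#' @return a logical matrix with exactly one foreground component.
#' @export
refineMask <- function(raw, radius = NULL) {
  if (sum(raw) == 0) stop("no wound region found: empty mask")
  if (is.null(radius)) radius <- max(1, round(3 * min(dim(raw)) / 512))
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- raw * 1
  m <- EBImage::closing(m, kern)
  m <- EBImage::opening(m, kern)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) stop("no wound region found: mask empty after refinement")
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  matrix(keep, nrow(raw), ncol(raw))
}

#' Crop an image to its wound bed
#'
#' Restricts an image to the bounding box of a wound mask; pixels outside
#' the mask are excluded from all downstream statistics (the cropped mask
#' travels with the image).
#'
#' @param img an \linkS4class{RGBImage}.
#' @param mask logical matrix matching the image shape.
#' @return list with \code{image} (bounding-box-cropped
#'   \linkS4class{RGBImage}), \code{mask} (cropped logical matrix) and
#'   \code{bbox} (\code{c(row1, row2, col1, col2)}).
#' @export
cropWound <- function(img, mask) {
  px <- pixels(img)
  if (!identical(dim(px)[1:2], dim(mask)))
    stop("image and mask shapes differ")
  if (sum(mask) == 0) stop("no wound region found: empty mask")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  ## keep at least the 16 x 16 pipeline minimum
  while (diff(rr) < 15 && (rr[1] > 1 || rr[2] < nrow(mask)))
    rr <- c(max(1, rr[1] - 1), min(nrow(mask), rr[2] + 1))
  while (diff(cc) < 15 && (cc[1] > 1 || cc[2] < ncol(mask)))
    cc <- c(max(1, cc[1] - 1), min(ncol(mask), cc[2] + 1))
  list(image = rgbImage(px[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE],
                        id = imageId(img)),
       mask = mask[rr[1]:rr[2], cc[1]:cc[2]],
       bbox = c(rr, cc))
}

#' Segment the wound bed of a photograph
#'
#' Convenience wrapper running the full segmentation stage: median
#' filtering, saturation-plane extraction, fuzzy-divergence threshold
#' selection and morphological refinement.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param window median-filter window (odd, default 5).
#' @return a \linkS4class{SegmentationResult}.
#' @export
segmentWound <- function(img, window = 5L) {
  selectThreshold(sChannel(medianFilterRGB(img, window)))
}

#' Dice overlap between two masks
#'
#' @param a,b logical matrices of identical shape.
#' @return \code{2|A∩B| / (|A|+|B|)}; 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
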