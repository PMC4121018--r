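#' @include color-model.R
NULL

## Per-channel feature names, in fixed order: 5 color moments + 10 texture
## features (entropy, 3 local contrasts, 3 rotation-invariant LBP means,
## 3 local-variance means) = 15 per channel, 675 over the 45 channels.
.FEATS <- c("mean", "std", "variance", "skewness", "kurtosis", "entropy",
            "lc_mean", "lc_median", "lc_mode",
            "lbp_r1", "lbp_r2", "lbp_r3", "var_r1", "var_r2", "var_r3")

#' The 675-entry feature manifest
#'
#' @return character vector of the 675 feature names, channel-major:
#'   for each channel of \code{\link{channelManifest}}, the 15 per-channel
#'   features in the order mean, std, variance, skewness, kurtosis,
#'   entropy, lc_mean, lc_median, lc_mode, lbp_r1..r3, var_r1..r3.
#' @export
featureManifest <- function() {
  ch <- channelManifest()$channel
  as.vector(t(outer(ch, .FEATS, paste, sep = ".")))
}

#' Color moments of a region
#'
#' Population (1/N) moments of the region's pixel values: mean, standard
#' deviation, variance, skewness and kurtosis (non-excess). For a
#' zero-variance region, skewness and kurtosis are defined as 0 so
#' downstream learners never see non-finite values.
#'
#' @param values numeric vector of region pixel values (non-empty).
#' @return named numeric vector \code{(mean, std, variance, skewness,
#'   kurtosis)}.
#' @export
colorMoments <- function(values) {
  if (length(values) == 0) stop("empty region")
  m <- mean(values)
  v <- mean((values - m)^2)
  s <- sqrt(v)
  if (s > 0) {
    z <- (values - m) / s
    sk <- mean(z^3); ku <- mean(z^4)
  } else sk <- ku <- 0
  c(mean = m, std = s, variance = v, skewness = sk, kurtosis = ku)
}

#' Shannon entropy of a region
#'
#' Values are quantized to 256 equal bins over the declared range and the
#' entropy \code{-sum(p log2 p)} of the bin occupancy is returned, in bits.
#'
#' @param values numeric vector of region pixel values.
#' @param range declared channel range used for binning.
#' @return entropy in bits (0 for a constant region).
#' @export
shannonEntropy <- function(values, range = c(0, 255)) {
  if (length(values) == 0) stop("empty region")
  q <- floor((values - range[1]) / (range[2] - range[1]) * 256)
  q[q > 255] <- 255; q[q < 0] <- 0
  p <- tabulate(q + 1L, nbins = 256L)
  p <- p[p > 0] / length(values)
  -sum(p * log2(p))
}

#' Local contrast of a region
#'
#' The normalized difference \code{(T - A)/(T + A)} between the mean
#' \code{T} of values at or above a central measure and the mean \code{A}
#' of values below it. The central measure is the region mean, median, or
#' mode; the mode is taken on the 256-bin quantized values (smallest bin
#' on ties) and the contrast for \code{center = "mode"} is computed on the
#' quantized scale. Returns 0 when either side is empty or \code{T + A}
#' is 0.
#'
#' @param values numeric vector of region pixel values (at least 2).
#' @param center \code{"mean"}, \code{"median"} or \code{"mode"}.
#' @param range declared channel range (for mode quantization).
#' @return a scalar in \code{[-1, 1]}.
#' @export
localContrast <- function(values, center = c("mean", "median", "mode"),
                          range = c(0, 255)) {
  if (length(values) < 2) stop("local contrast needs at least 2 values")
  center <- match.arg(center)
  if (center == "mode") {
    q <- floor((values - range[1]) / (range[2] - range[1]) * 256)
    q[q > 255] <- 255; q[q < 0] <- 0
    cnt <- tabulate(q + 1L, nbins = 256L)
    c0 <- which.max(cnt) - 1L          # smallest modal bin on ties
    values <- q
  } else {
    c0 <- if (center == "mean") mean(values) else stats::median(values)
  }
  hi <- values >= c0
  if (!any(hi) || all(hi)) return(0)
  T <- mean(values[hi]); A <- mean(values[!hi])
  if (T + A == 0) return(0)
  (T - A) / (T + A)
}

## ---------------------------------------------------------------------------
## Local binary patterns

#' Local binary pattern codes
#'
#' \code{lbpCode} thresholds P circular neighbors against the center gray
#' value (bit p set iff \code{g_p >= g_c}) and packs them into an integer
#' \code{sum(s_p 2^p)}. \code{lbpRotationInvariant} reduces codes to their
#' minimum over all P circular bit rotations, making the pattern invariant
#' to image rotation. \code{lbpRICode} combines both steps.
#'
#' @param neighbors numeric vector of P neighbor gray values (ordered
#'   counter-clockwise around the circle).
#' @param center the center pixel's gray value.
#' @param code integer LBP code(s) (vectorized).
#' @param P number of neighbors (bits).
#' @return an integer code (or vector of codes).
#' @export
lbpCode <- function(neighbors, center) {
  s <- as.numeric(neighbors >= center)
  sum(s * 2^(seq_along(s) - 1))
}

#' @rdname lbpCode
#' @export
lbpRotationInvariant <- function(code, P) {
  best <- code
  if (P > 1) for (i in 1:(P - 1)) {
    lo <- code %% 2^i
    best <- pmin(best, code %/% 2^i + lo * 2^(P - i))
  }
  best
}

#' @rdname lbpCode
#' @export
lbpRICode <- function(neighbors, center) {
  lbpRotationInvariant(lbpCode(neighbors, center), length(neighbors))
}

#' Local variance of a sampled circular neighborhood
#'
#' The rotation-invariant contrast measure paired with LBP:
#' \code{VAR = (1/P) sum_p (g_p - mean(g))^2} over the P sampled neighbor
#' gray values.
#'
#' @param values numeric vector of neighbor gray values.
#' @return the population variance of the neighborhood.
#' @export
neighborVariance <- function(values) mean((values - mean(values))^2)

## circular sampling geometry: P = 8R neighbors at angles 2*pi*p/P,
## offsets rounded so axis-aligned samples land exactly on pixels
.circularOffsets <- function(R) {
  P <- 8L * R
  ang <- 2 * pi * (seq_len(P) - 1) / P
  list(P = P, dx = round(R * cos(ang), 8), dy = round(-R * sin(ang), 8))
}

.shiftMat <- function(m, dy, dx, fill = NA) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r1 <- max(1, 1 - dy); r2 <- min(h, h - dy)
  c1 <- max(1, 1 - dx); c2 <- min(w, w - dx)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + dy):(r2 + dy), (c1 + dx):(c2 + dx)]
  out
}

## bilinear support of neighbor p: integer offsets and weights (> 0 only)
.bilinearSupport <- function(dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  off <- rbind(c(y0, x0), c(y0, x0 + 1), c(y0 + 1, x0), c(y0 + 1, x0 + 1))
  wt <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  keep <- wt > 1e-9
  list(off = off[keep, , drop = FALSE], wt = wt[keep])
}

## Per-pixel rotation-invariant LBP code and local-variance maps for one
## quantized channel at radius R. Border pixels whose circle leaves the
## image are NA.
.lbpVarMaps <- function(q, R) {
  geo <- .circularOffsets(R)
  P <- geo$P
  mu <- 0; m2 <- 0; code <- 0
  for (p in seq_len(P)) {
    sup <- .bilinearSupport(geo$dy[p], geo$dx[p])
    np <- 0
    for (k in seq_along(sup$wt))
      np <- np + sup$wt[k] * .shiftMat(q, sup$off[k, 1], sup$off[k, 2])
    code <- code + (np >= q) * 2^(p - 1)
    mu <- mu + np
    m2 <- m2 + np^2
  }
  mu <- mu / P
  v <- m2 / P - mu^2
  v[!is.na(v) & v < 1e-9] <- 0     # zap accumulator float residue
  list(code = matrix(lbpRotationInvariant(as.vector(code), P), nrow(q)),
       var = v, P = P)
}

## region validity at radius R: center in mask and the full bilinear
## support of every neighbor inside the mask
.lbpValid <- function(mask, R) {
  geo <- .circularOffsets(R)
  valid <- mask
  for (p in seq_len(geo$P)) {
    sup <- .bilinearSupport(geo$dy[p], geo$dx[p])
    for (k in seq_along(sup$wt))
      valid <- valid & .shiftMat(mask, sup$off[k, 1], sup$off[k, 2],
                                 fill = FALSE)
  }
  valid
}

#' Rotation-invariant LBP and local-variance features of a region
#'
#' Samples P = 8R neighbors on a circle of radius R (bilinear
#' interpolation), computes per-pixel rotation-invariant LBP codes and
#' the neighbor variance \code{VAR = mean((g_p - mean(g_p))^2)}, and
#' averages both over all region pixels whose entire neighborhood lies
#' inside the mask (no padding, so background never contaminates tissue
#' texture). If no pixel has full support, both features are 0 with a
#' warning.
#'
#' @param channel a \linkS4class{ChannelImage} or numeric matrix (values
#'   are quantized to the 0..255 bin scale using the declared range).
#' @param mask logical region mask.
#' @param R circle radius, 1, 2 or 3 (P = 8, 16, 24).
#' @return named numeric vector \code{(lbp, var)}.
#' @export
lbpVarFeatures <- function(channel, mask, R) {
  q <- if (is(channel, "ChannelImage")) .quantize256(channel)
       else round(channel)
  if (!R %in% 1:3) stop("'R' must be 1, 2 or 3")
  maps <- .lbpVarMaps(q, R)
  valid <- .lbpValid(mask, R)
  if (!any(valid)) {
    warning("no pixel with full radius-", R, " neighborhood inside mask")
    return(c(lbp = 0, var = 0))
  }
  c(lbp = mean(maps$code[valid]), var = mean(maps$var[valid]))
}

## ---------------------------------------------------------------------------
## Full descriptor

## features of one region given precomputed channel data
.regionFeatures <- function(chans, lbpmaps, mask, validCache) {
  out <- numeric(0)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    raw <- pixels(ch)[mask]
    q <- lbpmaps[[nm]]$q
    mom <- colorMoments(raw)
    ent <- shannonEntropy(raw, channelRange(ch))
    lcs <- c(localContrast(raw, "mean"), localContrast(raw, "median"),
             localContrast(q[mask] , "mode", c(0, 255)))
    lbp <- var3 <- numeric(3)
    for (R in 1:3) {
      valid <- validCache[[R]]
      if (any(valid)) {
        lbp[R] <- mean(lbpmaps[[nm]]$maps[[R]]$code[valid])
        var3[R] <- mean(lbpmaps[[nm]]$maps[[R]]$var[valid])
      }
    }
    out <- c(out, mom, ent, lcs, lbp, var3)
  }
  names(out) <- featureManifest()
  out
}

#' Extract the 675-entry descriptor of one tissue region
#'
#' Converts the image to all 45 color channels and computes, per channel,
#' 5 color moments and 10 texture features over the region's masked
#' pixels: Shannon entropy, local contrast about the mean/median/mode,
#' and mean rotation-invariant LBP and local-variance at radii 1, 2, 3.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param region a \linkS4class{TissueRegion} (or a logical mask matrix).
#' @return named numeric vector of length 675, in manifest order.
#' @export
extractFeatures <- function(img, region) {
  if (is.matrix(region)) region <- tissueRegion(region, imageId = imageId(img))
  tab <- extractFeatureTable(img, list(region))
  v <- as.numeric(tab[1, featureManifest()])
  names(v) <- featureManifest()
  v
}

#' Extract features for several regions of one image
#'
#' Channel conversions and LBP/VAR maps are computed once per image and
#' shared across regions, which is how labeled training tables are built
#' efficiently.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param regions list of \linkS4class{TissueRegion}s within the image.
#' @return data frame with columns \code{image_id}, \code{region_id},
#'   \code{label} and the 675 feature columns in manifest order.
#' @export
extractFeatureTable <- function(img, regions) {
  d <- dim(pixels(img))[1:2]
  for (rg in regions)
    if (!identical(dim(regionMask(rg)), d))
      stop("region mask shape does not match image")
  chans <- convertAllSpaces(img)
  lbpmaps <- lapply(chans, function(ch) {
    q <- .quantize256(ch)
    list(q = q, maps = lapply(1:3, function(R) .lbpVarMaps(q, R)))
  })
  rows <- lapply(seq_along(regions), function(i) {
    mask <- regionMask(regions[[i]])
    validCache <- lapply(1:3, function(R) .lbpValid(mask, R))
    .regionFeatures(chans, lbpmaps, mask, validCache)
  })
  feat <- do.call(rbind, rows)
  out <- data.frame(
    image_id = imageId(img),
    region_id = sprintf("%s_r%d", imageId(img), seq_along(regions)),
    label = vapply(regions, regionLabel, ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(feat, check.names = FALSE))
}

#' Read/write feature tables as CSV
#'
#' The CSV carries a header of \code{image_id}, \code{region_id},
#' \code{label} plus the 675 named feature columns; the reader restores
#' it bit-identically (column names are not mangled).
#'
#' @param table a feature data frame from \code{\link{extractFeatureTable}}.
#' @param path CSV file path.
#' @return \code{readFeatureTable}: the restored data frame.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
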