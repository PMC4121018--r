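#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Channel manifest: 15 color spaces x 3 components, in fixed order.
## Video-matrix spaces (YUV/YIQ/YCbCr/YDbDr/YPbPr) use ITU-R BT.601 on
## gamma-encoded sRGB; YCbCrJPEG is the full-range JFIF variant. XYZ, Lab,
## Luv, LCH and LMS assume sRGB primaries with a D65 white point; LMS is
## XYZ followed by the CAT02 matrix.

.SPACES <- list(
  RGB       = list(comp = c("R", "G", "B"),
                   range = list(c(0, 255), c(0, 255), c(0, 255))),
  HSI       = list(comp = c("H", "S", "I"),
                   range = list(c(0, 360), c(0, 1), c(0, 255))),
  XYZ       = list(comp = c("X", "Y", "Z"),
                   range = list(c(0, 0.96), c(0, 1), c(0, 1.09))),
  Lab       = list(comp = c("L", "a", "b"),
                   range = list(c(0, 100), c(-128, 127), c(-128, 127))),
  Luv       = list(comp = c("L", "u", "v"),
                   range = list(c(0, 100), c(-134, 220), c(-140, 122))),
  LCH       = list(comp = c("L", "C", "H"),
                   range = list(c(0, 100), c(0, 180), c(0, 360))),
  HSV       = list(comp = c("H", "S", "V"),
                   range = list(c(0, 360), c(0, 1), c(0, 1))),
  HSL       = list(comp = c("H", "S", "L"),
                   range = list(c(0, 360), c(0, 1), c(0, 1))),
  YUV       = list(comp = c("Y", "U", "V"),
                   range = list(c(0, 1), c(-0.436, 0.436), c(-0.615, 0.615))),
  YIQ       = list(comp = c("Y", "I", "Q"),
                   range = list(c(0, 1), c(-0.596, 0.596), c(-0.523, 0.523))),
  LMS       = list(comp = c("L", "M", "S"),
                   range = list(c(0, 1.1), c(0, 1.1), c(0, 1.1))),
  YCbCr     = list(comp = c("Y", "Cb", "Cr"),
                   range = list(c(0, 255), c(0, 255), c(0, 255))),
  YCbCrJPEG = list(comp = c("Y", "Cb", "Cr"),
                   range = list(c(0, 255), c(0, 255), c(0, 255))),
  YDbDr     = list(comp = c("Y", "Db", "Dr"),
                   range = list(c(0, 1), c(-1.334, 1.334), c(-1.334, 1.334))),
  YPbPr     = list(comp = c("Y", "Pb", "Pr"),
                   range = list(c(0, 1), c(-0.5, 0.5), c(-0.5, 0.5)))
)

.CAT02 <- matrix(c(0.7328, 0.4286, -0.1624,
                   -0.7036, 1.6975, 0.0061,
                   0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)

#' The 45-channel manifest
#'
#' The fixed, documented order of the 45 color channels (15 spaces x 3
#' components) used for feature extraction. All feature vectors and CSV
#' columns follow this order.
#'
#' @param path optional path; when given, the manifest is also written as
#'   a JSON array so feature tables are self-describing.
#' @return a data frame with columns \code{channel} (\code{"space.component"}),
#'   \code{space}, \code{component}, \code{lo}, \code{hi} (declared range).
#' @export
channelManifest <- function(path = NULL) {
  rows <- do.call(rbind, lapply(names(.SPACES), function(sp) {
    s <- .SPACES[[sp]]
    data.frame(channel = paste(sp, s$comp, sep = "."), space = sp,
               component = s$comp,
               lo = vapply(s$range, `[`, 0, 1),
               hi = vapply(s$range, `[`, 0, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (!is.null(path))
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA)
  rows
}

## hue in degrees shared by HSV/HSL (undefined -> 0)
.hueDeg <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- numeric(length(r))
  i <- d > 0 & mx == r
  h[i] <- ((g[i] - b[i]) / d[i]) %% 6
  i <- d > 0 & mx == g & mx != r
  h[i] <- (b[i] - r[i]) / d[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- (r[i] - g[i]) / d[i] + 4
  (h * 60) %% 360
}

#' Convert an RGB image to HSI
#'
#' The geometric hue-saturation-intensity model: \code{I = (R+G+B)/3},
#' \code{S = 1 - 3 min(R,G,B)/(R+G+B)} (0 for black pixels), and hue from
#' the arccos formulation in degrees \code{[0, 360)}. Saturation measures
#' how far a color is from gray, which is what separates a wound bed from
#' surrounding skin.
#'
#' @param img an \linkS4class{RGBImage}.
#' @return a named list of three \linkS4class{ChannelImage}s (\code{H},
#'   \code{S}, \code{I}).
#' @export
toHSI <- function(img) {
  px <- pixels(img)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  s3 <- r + g + b
  I <- s3 / 3
  S <- ifelse(s3 == 0, 0, 1 - 3 * pmin(r, g, b) / s3)
  num <- ((r - g) + (r - b)) / 2
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  th <- acos(pmin(pmax(ifelse(den == 0, 1, num / den), -1), 1)) * 180 / pi
  H <- ifelse(den == 0, 0, ifelse(b <= g, th, 360 - th))
  list(H = channelImage(H, "HSI", "H", c(0, 360)),
       S = channelImage(S, "HSI", "S", c(0, 1)),
       I = channelImage(I, "HSI", "I", c(0, 255)))
}

#' The saturation plane on an 8-bit scale
#'
#' Extracts the HSI saturation component and scales it linearly from
#' \code{[0, 1]} to \code{[0, 255]} (real-valued), ready for the
#' 255-candidate threshold search of \code{\link{selectThreshold}}.
#'
#' @param img an \linkS4class{RGBImage}.
#' @return a \linkS4class{ChannelImage} with values in \code{[0, 255]}.
#' @export
sChannel <- function(img) {
  s <- toHSI(img)$S
  channelImage(pixels(s) * 255, "HSI", "S8", c(0, 255))
}

#' Convert an RGB image into all 45 color channels
#'
#' Produces the fixed list of 45 \linkS4class{ChannelImage}s documented by
#' \code{\link{channelManifest}}. Conversions follow the standard published
#' transforms: sRGB primaries and D65 white point for XYZ/Lab/Luv/LCH/LMS
#' (LMS being XYZ through the CAT02 matrix), ITU-R BT.601 matrices on
#' gamma-encoded values for YUV/YIQ/YCbCr/YDbDr/YPbPr, and the full-range
#' JFIF variant for YCbCrJPEG. Channels keep their native numeric ranges.
#'
#' @param img an \linkS4class{RGBImage}.
#' @return a named list of 45 \linkS4class{ChannelImage}s, in manifest order.
#' @export
convertAllSpaces <- function(img) {
  px <- pixels(img)
  h <- dim(px)[1]; w <- dim(px)[2]
  r <- as.vector(px[, , 1]) / 255
  g <- as.vector(px[, , 2]) / 255
  b <- as.vector(px[, , 3]) / 255
  rgb01 <- cbind(r, g, b)

  xyz <- grDevices::convertColor(rgb01, "sRGB", "XYZ")
  lab <- grDevices::convertColor(rgb01, "sRGB", "Lab")
  luv <- grDevices::convertColor(rgb01, "sRGB", "Luv")
  lch <- cbind(lab[, 1], sqrt(lab[, 2]^2 + lab[, 3]^2),
               (atan2(lab[, 3], lab[, 2]) * 180 / pi) %% 360)
  lms <- xyz %*% t(.CAT02)

  hue <- .hueDeg(r, g, b)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  hsv <- cbind(hue, ifelse(mx == 0, 0, d / mx), mx)
  l2 <- (mx + mn) / 2
  hsl <- cbind(hue, ifelse(d == 0, 0, d / (1 - abs(2 * l2 - 1))), l2)

  y <- 0.299 * r + 0.587 * g + 0.114 * b        # BT.601 luma
  yuv <- cbind(y, 0.492 * (b - y), 0.877 * (r - y))
  yiq <- cbind(y, 0.595716 * r - 0.274453 * g - 0.321263 * b,
               0.211456 * r - 0.522591 * g + 0.311135 * b)
  pb <- (b - y) / 1.772; pr <- (r - y) / 1.402
  ycc <- cbind(16 + 219 * y, 128 + 224 * pb, 128 + 224 * pr)
  yccj <- cbind(255 * y, 128 + 255 * pb, 128 + 255 * pr)
  ydd <- cbind(y, 1.505 * (b - y), -1.902 * (r - y))
  ypp <- cbind(y, pb, pr)

  hsi <- toHSI(img)
  planes <- list(
    RGB = cbind(r, g, b) * 255,
    HSI = cbind(as.vector(pixels(hsi$H)), as.vector(pixels(hsi$S)),
                as.vector(pixels(hsi$I))),
    XYZ = xyz, Lab = lab, Luv = luv, LCH = lch, HSV = hsv, HSL = hsl,
    YUV = yuv, YIQ = yiq, LMS = lms, YCbCr = ycc, YCbCrJPEG = yccj,
    YDbDr = ydd, YPbPr = ypp)

  out <- list()
  for (sp in names(.SPACES)) {
    s <- .SPACES[[sp]]
    for (k in 1:3) {
      v <- matrix(planes[[sp]][, k], h, w)
      rg <- s$range[[k]]
      v <- pmin(pmax(v, rg[1]), rg[2])   # guard sub-pixel numeric overshoot
      out[[paste(sp, s$comp[k], sep = ".")]] <-
        channelImage(v, sp, s$comp[k], rg)
    }
  }
  out
}

## Quantize a channel to the 256-bin integer scale 0..255 over its
## declared range. Used for entropy, mode and LBP/VAR stability.
.quantize256 <- function(ch) {
  rg <- channelRange(ch)
  v <- (pixels(ch) - rg[1]) / (rg[2] - rg[1])
  q <- floor(v * 256)
  q[q > 255] <- 255L
  q[q < 0] <- 0L
  q
}
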