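#' @include AllClasses.R
NULL

#' Read a wound photograph
#'
#' Reads a PNG, JPEG or TIFF raster into an \linkS4class{RGBImage}.
#' Grayscale inputs are replicated to three planes and an alpha plane, if
#' present, is dropped. Rasters with more than 8 bits per sample are
#' linearly rescaled to \code{[0, 255]} with a warning.
#'
#' @param path path to an image file.
#' @param id identifier stored with the image; defaults to the file name.
#' @return an \linkS4class{RGBImage}.
#' @export
readWoundImage <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("cannot read image: '", path, "' not found")
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      a <- tiff::readTIFF(path, info = TRUE)   # normalized to [0, 1]
      bits <- attr(a, "bits.per.sample")
      if (!is.null(bits) && bits > 8L)
        warning("'", path, "': ", bits,
                " bits per sample, rescaling to [0, 255]")
      a * 255
    } else {
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) == 3L) a <- aperm(a, c(2, 1, 3)) else a <- t(a)
      a * 255
    }
  }, error = function(e) {
    stop("cannot decode image '", path, "': ", conditionMessage(e))
  })
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  rgbImage(round(pmin(pmax(px, 0), 255)), id = id)
}

#' Write an image or mask as PNG
#'
#' Masks are written as single-channel PNG with values 0/255.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param mask a logical matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeWoundImage <- function(img, path) {
  png::writePNG(pixels(img) / 255, path)
  invisible(path)
}

#' @rdname writeWoundImage
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' @param path path to a mask PNG (values 0/255).
#' @return a logical matrix.
#' @export
readMaskPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a >= 0.5
}

#' Per-channel median filtering of an RGB image
#'
#' Replaces each pixel of each channel independently by the median over a
#' square window centered on it; the default 5 x 5 window removes the
#' salt-and-pepper impulses typical of rapid clinical photography while
#' preserving wound edges. Image borders are handled by edge replication,
#' so a constant image passes through unchanged and the output range never
#' leaves the input range.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param window odd window side length, at least 3.
#' @return the filtered \linkS4class{RGBImage}.
#' @export
medianFilterRGB <- function(img, window = 5L) {
  if (window %% 2 != 1 || window < 3)
    stop("'window' must be an odd integer >= 3")
  px <- pixels(img)
  h <- dim(px)[1]; w <- dim(px)[2]
  r <- (window - 1L) / 2L
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))      # replicated border index
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  out <- px
  for (k in 1:3) {
    pad <- px[ri, ci, k] / 255
    f <- EBImage::medianFilter(pad, r)
    out[, , k] <- round(f[(r + 1):(r + h), (r + 1):(r + w)] * 255)
  }
  rgbImage(out, id = imageId(img))
}
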