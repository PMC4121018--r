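#' @include AllGenerics.R
NULL

## The three tissue classes, in their fixed decision order. Ties in any
## classifier vote are broken toward the earlier class.
.TISSUES <- c("granulation", "slough", "necrotic")

#' Wound tissue class labels
#'
#' @return \code{c("granulation", "slough", "necrotic")}, the fixed class
#'   order used throughout the package (confusion-matrix rows/columns,
#'   classifier tie-breaking).
#' @export
tissueClasses <- function() .TISSUES

## ---------------------------------------------------------------------------
## RGBImage

#' RGBImage: an 8-bit color photograph
#'
#' A height x width x 3 array of integer-valued intensities in
#' \code{[0, 255]} plus a source identifier. Images smaller than 16 x 16
#' are rejected: the texture operators need at least that much support.
#'
#' @slot pixels numeric array, height x width x 3, values in \code{[0, 255]}.
#' @slot id character scalar naming the source.
#' @export
setClass("RGBImage", representation(pixels = "array", id = "character"))

setValidity("RGBImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("'pixels' must be a height x width x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("image must be at least 16 x 16 pixels")
  if (!all(is.finite(object@pixels)))
    return("pixel intensities must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel intensities must lie in [0, 255]")
  if (length(object@id) != 1L) return("'id' must be a single string")
  TRUE
})

#' Construct an RGBImage
#'
#' @param pixels height x width x 3 numeric array in \code{[0, 255]}
#'   (a matrix is replicated across the three planes).
#' @param id source identifier.
#' @return an \linkS4class{RGBImage}.
#' @export
rgbImage <- function(pixels, id = "image") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  new("RGBImage", pixels = pixels, id = as.character(id))
}

#' @rdname pixels
#' @export
setMethod("pixels", "RGBImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("imageId", "RGBImage", function(x) x@id)

#' @export
setMethod("dim", "RGBImage", function(x) dim(x@pixels))

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage '%s': %d x %d, range [%d, %d]\n", object@id,
              d[1], d[2], min(object@pixels), max(object@pixels)))
})

## ---------------------------------------------------------------------------
## ChannelImage

#' ChannelImage: one scalar plane of a color-space component
#'
#' @slot pixels numeric matrix of component values.
#' @slot space color-space name (one of the 15 supported spaces).
#' @slot component component name within the space (e.g. \code{"S"}).
#' @slot range declared numeric range \code{c(lo, hi)} of the component;
#'   quantization to 256 bins is always performed over this range.
#' @export
setClass("ChannelImage",
         representation(pixels = "matrix", space = "character",
                        component = "character", range = "numeric"))

setValidity("ChannelImage", function(object) {
  if (length(object@range) != 2L || diff(object@range) <= 0)
    return("'range' must be c(lo, hi) with lo < hi")
  if (!all(is.finite(object@pixels)))
    return("channel values must be finite")
  tol <- 1e-6 * diff(object@range)
  if (min(object@pixels) < object@range[1] - tol ||
      max(object@pixels) > object@range[2] + tol)
    return(sprintf("values outside declared range [%g, %g] for %s.%s",
                   object@range[1], object@range[2],
                   object@space, object@component))
  TRUE
})

channelImage <- function(pixels, space, component, range) {
  new("ChannelImage", pixels = pixels, space = space,
      component = component, range = as.numeric(range))
}

#' @rdname pixels
#' @export
setMethod("pixels", "ChannelImage", function(x) x@pixels)

#' Channel identity and declared range
#'
#' @param x a \linkS4class{ChannelImage}.
#' @return \code{channelName}: the \code{"space.component"} string;
#'   \code{channelRange}: the declared \code{c(lo, hi)}.
#' @export
channelName <- function(x) paste(x@space, x@component, sep = ".")

#' @rdname channelName
#' @export
channelRange <- function(x) x@range

#' @export
setMethod("dim", "ChannelImage", function(x) dim(x@pixels))

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage %s: %d x %d, declared range [%g, %g]\n",
              channelName(object), nrow(object@pixels), ncol(object@pixels),
              object@range[1], object@range[2]))
})

## ---------------------------------------------------------------------------
## SegmentationResult

#' SegmentationResult: outcome of fuzzy-divergence threshold selection
#'
#' @slot threshold selected gray level in \code{[1, 255]}.
#' @slot divergence total fuzzy divergence at the optimum (non-negative).
#' @slot rawMask logical matrix, \code{channel >= threshold}.
#' @slot refinedMask logical matrix after morphological refinement;
#'   contains exactly one 8-connected foreground component.
#' @export
setClass("SegmentationResult",
         representation(threshold = "numeric", divergence = "numeric",
                        rawMask = "matrix", refinedMask = "matrix"))

setValidity("SegmentationResult", function(object) {
  if (object@threshold < 1 || object@threshold > 255 ||
      object@threshold != round(object@threshold))
    return("'threshold' must be an integer gray level in [1, 255]")
  if (object@divergence < 0) return("'divergence' must be non-negative")
  if (!identical(dim(object@rawMask), dim(object@refinedMask)))
    return("raw and refined masks must have identical shape")
  if (sum(object@refinedMask) > 0) {
    ncomp <- max(EBImage::bwlabel(object@refinedMask * 1))
    if (ncomp != 1L)
      return("refined mask must contain exactly one connected component")
  }
  TRUE
})

#' @rdname threshold
#' @export
setMethod("threshold", "SegmentationResult", function(x) x@threshold)

#' @rdname threshold
#' @export
setMethod("divergence", "SegmentationResult", function(x) x@divergence)

#' @rdname threshold
#' @export
setMethod("rawMask", "SegmentationResult", function(x) x@rawMask)

#' @rdname threshold
#' @export
setMethod("refinedMask", "SegmentationResult", function(x) x@refinedMask)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: threshold %d, divergence %.4f, wound area %d px\n",
    object@threshold, object@divergence, sum(object@refinedMask)))
})

## ---------------------------------------------------------------------------
## TissueRegion

#' TissueRegion: a labeled (or unlabeled) region of a wound image
#'
#' @slot imageId identifier of the parent image.
#' @slot mask logical matrix selecting the region's pixels (at least 16).
#' @slot label \code{"granulation"}, \code{"slough"}, \code{"necrotic"} or
#'   \code{"unlabeled"}.
#' @export
setClass("TissueRegion",
         representation(imageId = "character", mask = "matrix",
                        label = "character"))

setValidity("TissueRegion", function(object) {
  if (!object@label %in% c(.TISSUES, "unlabeled"))
    return("unknown tissue label")
  if (sum(object@mask) < 16L)
    return("region mask must contain at least 16 pixels")
  TRUE
})

#' Construct a TissueRegion
#'
#' @param mask logical matrix with at least 16 \code{TRUE} pixels.
#' @param label tissue class or \code{"unlabeled"}.
#' @param imageId identifier of the parent image.
#' @return a \linkS4class{TissueRegion}.
#' @export
tissueRegion <- function(mask, label = "unlabeled", imageId = "image") {
  new("TissueRegion", imageId = as.character(imageId),
      mask = mask, label = label)
}

#' @rdname tissueRegion
#' @param x a \code{TissueRegion}.
#' @export
regionLabel <- function(x) x@label

#' @rdname tissueRegion
#' @export
regionMask <- function(x) x@mask

setMethod("show", "TissueRegion", function(object) {
  cat(sprintf("TissueRegion (%s) in '%s': %d px\n", object@label,
              object@imageId, sum(object@mask)))
})

## ---------------------------------------------------------------------------
## FeatureSelection

#' FeatureSelection: one-way F ranking of feature columns
#'
#' @slot table data frame with columns \code{feature}, \code{statistic}
#'   (the F value), \code{p.value} and \code{retained}.
#' @slot threshold the F cutoff used; features with \code{F > threshold}
#'   are retained.
#' @export
setClass("FeatureSelection",
         representation(table = "data.frame", threshold = "numeric"))

setValidity("FeatureSelection", function(object) {
  need <- c("feature", "statistic", "p.value", "retained")
  if (!all(need %in% names(object@table)))
    return("selection table must have feature/statistic/p.value/retained")
  if (any(object@table$statistic < 0, na.rm = TRUE))
    return("F statistics must be non-negative")
  TRUE
})

#' @rdname retainedFeatures
#' @export
setMethod("retainedFeatures", "FeatureSelection",
          function(x) x@table$feature[x@table$retained])

#' @rdname retainedFeatures
#' @export
setMethod("selectionTable", "FeatureSelection", function(x) x@table)

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection: %d / %d features retained (F > %g)\n",
              sum(object@table$retained), nrow(object@table),
              object@threshold))
})

## ---------------------------------------------------------------------------
## Classifier models

#' BayesModel: Gaussian naive-Bayes tissue classifier
#'
#' Class priors are the training class frequencies; each retained feature
#' gets a per-class normal marginal fitted by maximum likelihood (1/N
#' variance) on z-scored features. Variances are floored at 1e-9 so
#' degenerate columns never produce non-finite densities.
#'
#' @slot priors named class prior probabilities (sum to 1).
#' @slot means,vars class x feature matrices of marginal parameters.
#' @slot center,scale standardization parameters learned on training data.
#' @slot features feature manifest (column names, in order).
#' @slot classes class labels in decision order.
#' @export
setClass("BayesModel",
         representation(priors = "numeric", means = "matrix", vars = "matrix",
                        center = "numeric", scale = "numeric",
                        features = "character", classes = "character"))

setValidity("BayesModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-8) return("priors must sum to 1")
  if (any(object@vars <= 0)) return("variances must be positive")
  TRUE
})

setMethod("show", "BayesModel", function(object) {
  cat(sprintf("BayesModel: %d classes, %d features\n",
              length(object@classes), length(object@features)))
})

#' SVMModel: kernel support-vector tissue classifier
#'
#' A soft-margin SVM trained on z-scored retained features, with
#' one-vs-one voting for the three classes. The decision machinery
#' (support vectors, dual coefficients, intercepts) is stored explicitly
#' so models serialize to plain JSON and prediction does not depend on
#' the training backend.
#'
#' @slot kernel list with \code{name} (linear/poly2/poly3/rbf),
#'   \code{degree}, \code{gamma}, \code{coef0}, \code{C}.
#' @slot svs support-vector matrix (rows standardized).
#' @slot coefs dual-coefficient matrix (libsvm one-vs-one layout).
#' @slot rho intercepts for the class pairs in order (1,2), (1,3), (2,3).
#' @slot nSV number of support vectors per class.
#' @slot center,scale standardization parameters.
#' @slot features feature manifest.
#' @slot classes class labels in decision order.
#' @export
setClass("SVMModel",
         representation(kernel = "list", svs = "matrix", coefs = "matrix",
                        rho = "numeric", nSV = "integer",
                        center = "numeric", scale = "numeric",
                        features = "character", classes = "character"))

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel (%s kernel): %d classes, %d features, %d SVs\n",
              object@kernel$name, length(object@classes),
              length(object@features), nrow(object@svs)))
})

## ---------------------------------------------------------------------------
## EvaluationReport

#' EvaluationReport: agreement between true and predicted tissue labels
#'
#' @slot counts 3 x 3 confusion matrix, rows = true class, columns =
#'   predicted class, in the order granulation, slough, necrotic.
#' @slot perClass tissue-wise accuracies in percent (diagonal / row total).
#' @slot macro mean of the defined per-class accuracies (percent).
#' @slot micro pooled accuracy, 100 * trace / total (percent).
#' @slot kappa Cohen's chance-corrected agreement in \code{[-1, 1]}.
#' @export
setClass("EvaluationReport",
         representation(counts = "matrix", perClass = "numeric",
                        macro = "numeric", micro = "numeric",
                        kappa = "numeric"))

setValidity("EvaluationReport", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) <= 0) return("confusion matrix must be non-empty")
  ok <- is.finite(object@perClass)
  if (any(object@perClass[ok] < 0 | object@perClass[ok] > 100))
    return("accuracies must lie in [0, 100]")
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa must lie in [-1, 1]")
  TRUE
})

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "EvaluationReport", function(x) x@counts)

#' @rdname confusionCounts
#' @export
setMethod("classAccuracy", "EvaluationReport", function(x) x@perClass)

#' @rdname confusionCounts
#' @export
setMethod("overallAccuracy", "EvaluationReport", function(x, type = c("macro", "micro")) {
  switch(match.arg(type), macro = x@macro, micro = x@micro)
})

#' @rdname confusionCounts
#' @export
setMethod("kappaStatistic", "EvaluationReport", function(x) x@kappa)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@counts)
  cat(sprintf("tissue-wise accuracy (%%): %s\n",
              paste(sprintf("%s %.2f", names(object@perClass),
                            object@perClass), collapse = ", ")))
  cat(sprintf("overall accuracy: macro %.2f%%, micro %.2f%%; kappa %.3f\n",
              object@macro, object@micro, object@kappa))
})

## ---------------------------------------------------------------------------
## WoundSpec

#' WoundSpec: parameters of a synthetic wound image
#'
#' Describes a skin-toned background with an embedded elliptical wound
#' partitioned into contiguous angular sectors of granulation, slough and
#' necrotic tissue. Defaults emulate a granulation-dominant chronic wound
#' (64.3 / 16.6 / 19.1 percent tissue proportions).
#'
#' @slot width,height image size in pixels.
#' @slot skin background skin color, RGB in \code{[0, 255]}.
#' @slot center,axes,rotation wound ellipse geometry (pixels, degrees).
#' @slot fractions tissue area fractions (granulation, slough, necrotic),
#'   non-negative, summing to 1.
#' @slot tissueColors 3 x 3 matrix of per-tissue mean RGB colors.
#' @slot jitterSd per-pixel Gaussian color jitter (gray levels).
#' @slot impulseFrac fraction of pixels hit by salt-and-pepper impulses.
#' @slot textureAmp amplitude of the sinusoidal texture (gray levels).
#' @slot seed RNG seed making generation deterministic.
#' @export
setClass("WoundSpec",
         representation(width = "numeric", height = "numeric",
                        skin = "numeric", center = "numeric",
                        axes = "numeric", rotation = "numeric",
                        fractions = "numeric", tissueColors = "matrix",
                        jitterSd = "numeric", impulseFrac = "numeric",
                        textureAmp = "numeric", seed = "numeric"))

setValidity("WoundSpec", function(object) {
  if (any(object@fractions < 0) || abs(sum(object@fractions) - 1) > 1e-6)
    return("tissue fractions must be non-negative and sum to 1")
  th <- object@rotation * pi / 180
  ## extreme extents of a rotated ellipse
  ex <- sqrt((object@axes[1] * cos(th))^2 + (object@axes[2] * sin(th))^2)
  ey <- sqrt((object@axes[1] * sin(th))^2 + (object@axes[2] * cos(th))^2)
  if (object@center[1] - ey < 1 || object@center[1] + ey > object@height ||
      object@center[2] - ex < 1 || object@center[2] + ex > object@width)
    return("wound ellipse must lie inside the image")
  if (any(object@skin < 0 | object@skin > 255) ||
      any(object@tissueColors < 0 | object@tissueColors > 255))
    return("colors must lie in [0, 255]")
  if (object@impulseFrac < 0 || object@impulseFrac > 1)
    return("impulse fraction must lie in [0, 1]")
  TRUE
})

setMethod("show", "WoundSpec", function(object) {
  cat(sprintf(
    "WoundSpec: %d x %d, fractions g/s/n = %.3f/%.3f/%.3f, seed %d\n",
    object@width, object@height, object@fractions[1], object@fractions[2],
    object@fractions[3], object@seed))
})
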