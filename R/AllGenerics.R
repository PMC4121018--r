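#' @import methods
NULL

#' Pixel data of an image or channel object
#'
#' @param x an \linkS4class{RGBImage} or \linkS4class{ChannelImage}.
#' @return For an \code{RGBImage}, a height x width x 3 numeric array of
#'   intensities in \code{[0, 255]}; for a \code{ChannelImage}, a numeric
#'   matrix in the channel's declared range.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' Accessors for segmentation results
#'
#' @param x a \linkS4class{SegmentationResult}.
#' @return \code{threshold}: the selected gray level in \code{[1, 255]};
#'   \code{divergence}: the total fuzzy divergence at the optimum;
#'   \code{rawMask}/\code{refinedMask}: logical matrices.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname threshold
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))

#' @rdname threshold
#' @export
setGeneric("rawMask", function(x) standardGeneric("rawMask"))

#' @rdname threshold
#' @export
setGeneric("refinedMask", function(x) standardGeneric("refinedMask"))

#' Accessors for feature-selection results
#'
#' @param x a \linkS4class{FeatureSelection}.
#' @return \code{retainedFeatures}: character vector of retained column
#'   names; \code{selectionTable}: data frame with one row per feature
#'   (F statistic, p value, retained flag).
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname retainedFeatures
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' Accessors for evaluation reports
#'
#' @param x an \linkS4class{EvaluationReport}.
#' @param type \code{"macro"} (mean of tissue-wise accuracies) or
#'   \code{"micro"} (pooled fraction correct).
#' @return \code{confusionCounts}: the 3 x 3 integer matrix (rows = true
#'   class, columns = predicted); \code{classAccuracy}: named per-class
#'   accuracies in percent; \code{overallAccuracy}: a percentage;
#'   \code{kappaStatistic}: Cohen's kappa in \code{[-1, 1]}.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname confusionCounts
#' @export
setGeneric("classAccuracy", function(x) standardGeneric("classAccuracy"))

#' @rdname confusionCounts
#' @export
setGeneric("overallAccuracy", function(x, type = c("macro", "micro"))
  standardGeneric("overallAccuracy"))

#' @rdname confusionCounts
#' @export
setGeneric("kappaStatistic", function(x) standardGeneric("kappaStatistic"))
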