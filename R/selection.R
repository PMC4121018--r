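#' @include AllClasses.R
NULL

#' One-way F ranking of feature columns
#'
#' Classic one-way ANOVA F per feature column (between-group mean square
#' over within-group mean square across the tissue classes), with the
#' p value from the F distribution on (k - 1, N - k) degrees of freedom.
#' Features with \code{F > threshold} are retained. Columns separating
#' the classes perfectly (zero within-class variance, nonzero
#' between-class variance) get \code{F = Inf} and are always retained;
#' columns that are constant everywhere get \code{F = 0}.
#'
#' The default cutoff of 21 is an operating point at which retained
#' features are significant far beyond p < 0.001 for typical class
#' counts; it is exposed so users can tighten or relax the selection.
#'
#' @param table feature data frame (as from
#'   \code{\link{extractFeatureTable}}) with a \code{label} column, or a
#'   numeric matrix/data frame of features.
#' @param labels class labels (taken from \code{table$label} when absent).
#' @param threshold retain features with \code{F > threshold}.
#' @param columns feature columns to rank; defaults to all numeric
#'   columns except bookkeeping ones.
#' @return a \linkS4class{FeatureSelection}.
#' @export
selectFeaturesF <- function(table, labels = NULL, threshold = 21,
                            columns = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(table)) stop("no labels supplied")
    labels <- table$label
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("feature selection needs at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 rows")
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       c("image_id", "region_id", "label"))
  x <- as.matrix(table[, columns, drop = FALSE])
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")

  n <- nrow(x); k <- nlevels(labels)
  idx <- split(seq_len(n), labels)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (ii in idx) {
    gm <- colMeans(x[ii, , drop = FALSE])
    ssb <- ssb + length(ii) * (gm - grand)^2
    ssw <- ssw + colSums((x[ii, , drop = FALSE] -
                            matrix(gm, length(ii), ncol(x), byrow = TRUE))^2)
  }
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  tab <- data.frame(feature = columns, statistic = f, p.value = p,
                    retained = f > threshold, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("FeatureSelection", table = tab, threshold = threshold)
}

#' Write a feature-selection report as CSV
#'
#' @param selection a \linkS4class{FeatureSelection}.
#' @param path CSV file path.
#' @export
writeSelectionCSV <- function(selection, path) {
  utils::write.csv(selectionTable(selection), path, row.names = FALSE)
  invisible(path)
}
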