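#' @include AllClasses.R
NULL

#' Confusion matrix of tissue labels
#'
#' @param true,predicted equal-length vectors of labels from the
#'   three-class set (row = true, column = predicted).
#' @param classes class order; defaults to \code{\link{tissueClasses}}.
#' @return 3 x 3 integer matrix of counts.
#' @export
tissueConfusion <- function(true, predicted, classes = tissueClasses()) {
  if (length(true) != length(predicted) || length(true) == 0)
    stop("label vectors must have equal, positive length")
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(true, classes), factor(predicted, classes))
  matrix(as.integer(cm), length(classes), length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Accuracies from a confusion matrix
#'
#' Tissue-wise accuracy is the diagonal count over the row total, in
#' percent. The macro overall accuracy is the mean of the defined
#' per-class accuracies; the micro overall accuracy is
#' \code{100 * trace / total}. A class with no true samples is reported
#' as \code{NA} and excluded from the macro mean with a warning.
#'
#' @param cm square count matrix (rows = true class).
#' @return list with \code{perClass} (named, percent), \code{macro} and
#'   \code{micro}.
#' @export
classAccuracies <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  per <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(per) <- rownames(cm)
  if (anyNA(per))
    warning("class(es) with no true samples excluded from macro accuracy: ",
            paste(names(per)[is.na(per)], collapse = ", "))
  list(perClass = per, macro = mean(per, na.rm = TRUE),
       micro = 100 * sum(diag(cm)) / sum(cm))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with
#' \code{p_o = trace/total} and \code{p_e = sum(row_i * col_i) / total^2};
#' defined as 1 in the degenerate case \code{p_e = p_o = 1}.
#'
#' @param cm square count matrix.
#' @return a scalar in \code{[-1, 1]}.
#' @export
cohensKappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Build an evaluation report
#'
#' @param cm a 3 x 3 confusion matrix, or \code{true} and \code{predicted}
#'   label vectors.
#' @param true,predicted label vectors (used when \code{cm} is missing).
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluationReport <- function(cm = NULL, true = NULL, predicted = NULL) {
  if (is.null(cm)) cm <- tissueConfusion(true, predicted)
  cm <- as.matrix(cm)
  acc <- classAccuracies(cm)
  new("EvaluationReport", counts = cm, perClass = acc$perClass,
      macro = acc$macro, micro = acc$micro, kappa = cohensKappa(cm))
}

#' Worked-example confusion matrices
#'
#' Five 3 x 3 wound-tissue confusion matrices — one for a naive-Bayes
#' classifier and one for each of the four SVM kernels — shipped with the
#' package as worked examples for the evaluation utilities and used by
#' the regression tests and the acceptance script. Rows are true classes,
#' columns predicted, in the order granulation, slough, necrotic. Row
#' totals are 222 granulation, 451 slough and 94 necrotic regions; the
#' second-order polynomial necrotic row is reconciled to that cohort size
#' (its published transcription summed to 96, inconsistent with the
#' published 73.40 percent accuracy, which equals 69/94; the ambiguous
#' slough off-diagonal cell is taken as 20).
#'
#' @return named list of five integer matrices (\code{bayes},
#'   \code{svm_linear}, \code{svm_poly2}, \code{svm_poly3},
#'   \code{svm_rbf}).
#' @export
referenceConfusionMatrices <- function() {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
                      package = "woundtissue", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$classifier), function(d) {
    d <- d[match(tissueClasses(), d$true_class), ]
    m <- as.matrix(d[, tissueClasses()])
    dimnames(m) <- list(true = tissueClasses(), predicted = tissueClasses())
    storage.mode(m) <- "integer"
    m
  })
  out[c("bayes", "svm_linear", "svm_poly2", "svm_poly3", "svm_rbf")]
}

#' Export an evaluation report
#'
#' \code{writeReportJSON} writes the matrix, tissue-wise/macro/micro
#' accuracies (percent, 2 decimals, round-half-even) and kappa as JSON;
#' \code{writeConfusionCSV} writes the count matrix as CSV.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output file path.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(
    confusion = confusionCounts(report),
    classes = rownames(confusionCounts(report)),
    accuracy = list(perClass = as.list(round(classAccuracy(report), 2)),
                    macro = round(overallAccuracy(report, "macro"), 2),
                    micro = round(overallAccuracy(report, "micro"), 2)),
    kappa = kappaStatistic(report))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReportJSON
#' @export
writeConfusionCSV <- function(report, path) {
  utils::write.csv(as.data.frame(confusionCounts(report)), path)
  invisible(path)
}
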