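#' @include AllClasses.R
NULL

## z-scoring baked into every model: constant columns get scale 1
.fitStandardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.applyStandardizer <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

## resolve the design matrix and labels from a feature table + selection
.designMatrix <- function(table, selection, labels) {
  if (is.null(labels)) {
    if (!"label" %in% names(table)) stop("no labels supplied")
    labels <- table$label
  }
  feats <- if (is.null(selection)) {
    setdiff(names(table)[vapply(table, is.numeric, TRUE)],
            c("image_id", "region_id", "label"))
  } else retainedFeatures(selection)
  if (length(feats) == 0) stop("empty retained feature set")
  classes <- intersect(c(tissueClasses(), sort(unique(labels))),
                       unique(labels))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  y <- factor(labels, levels = classes)
  if (any(table(y) < 2)) stop("every class needs at least 2 rows")
  x <- as.matrix(table[, feats, drop = FALSE])
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  list(x = x, y = y, features = feats, classes = classes)
}

.newdataMatrix <- function(model, newdata) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  newdata <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(model@features, names(newdata))
  if (length(miss) > 0)
    stop("query lacks model features: ", paste(head(miss, 3), collapse = ", "))
  x <- as.matrix(newdata[, model@features, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite query values")
  .applyStandardizer(x, model@center, model@scale)
}

## ---------------------------------------------------------------------------
## Gaussian naive Bayes

#' Fit the naive-Bayes tissue classifier
#'
#' Class priors are training class frequencies; each retained feature is
#' given per-class normal marginals fitted by maximum likelihood (1/N
#' variance) on z-scored features, with variances floored at 1e-9. The
#' posterior of a query is the prior-weighted product of marginal
#' densities, normalized over classes.
#'
#' @param table feature data frame with a \code{label} column.
#' @param selection optional \linkS4class{FeatureSelection}; when absent
#'   all feature columns are used.
#' @param labels class labels overriding \code{table$label}.
#' @return a \linkS4class{BayesModel}.
#' @export
fitBayes <- function(table, selection = NULL, labels = NULL) {
  d <- .designMatrix(table, selection, labels)
  std <- .fitStandardizer(d$x)
  xs <- .applyStandardizer(d$x, std$center, std$scale)
  k <- length(d$classes)
  means <- vars <- matrix(0, k, ncol(xs),
                          dimnames = list(d$classes, d$features))
  for (ci in seq_len(k)) {
    xi <- xs[d$y == d$classes[ci], , drop = FALSE]
    means[ci, ] <- colMeans(xi)
    vars[ci, ] <- pmax(colMeans(xi^2) - colMeans(xi)^2, 1e-9)
  }
  priors <- as.numeric(table(d$y)) / length(d$y)
  names(priors) <- d$classes
  new("BayesModel", priors = priors, means = means, vars = vars,
      center = std$center, scale = std$scale,
      features = d$features, classes = d$classes)
}

#' Predict tissue classes
#'
#' For a \linkS4class{BayesModel}, posteriors are computed in the log
#' domain and normalized to sum to 1; the predicted label is the
#' maximum-posterior class, ties broken by class order (granulation <
#' slough < necrotic). For an \linkS4class{SVMModel}, one-vs-one decision
#' values are computed from the stored support vectors and the majority
#' vote returned, with the same tie-breaking.
#'
#' @param object a fitted model.
#' @param newdata named numeric vector, matrix or data frame carrying the
#'   model's features.
#' @param type \code{"class"} for labels, \code{"posterior"} for the
#'   posterior matrix (Bayes) or \code{"votes"} (SVM).
#' @return character vector of labels, or a numeric matrix.
#' @export
setMethod("predict", "BayesModel", function(object, newdata,
                                            type = c("class", "posterior")) {
  type <- match.arg(type)
  xs <- .newdataMatrix(object, newdata)
  k <- length(object@classes)
  logpost <- matrix(0, nrow(xs), k, dimnames = list(NULL, object@classes))
  for (ci in seq_len(k)) {
    lp <- log(object@priors[ci])
    for (j in seq_len(ncol(xs)))
      lp <- lp + stats::dnorm(xs[, j], object@means[ci, j],
                              sqrt(object@vars[ci, j]), log = TRUE)
    logpost[, ci] <- lp
  }
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  if (type == "posterior") return(post)
  object@classes[apply(post, 1, which.max)]
})

## ---------------------------------------------------------------------------
## Kernel SVM

.kernelSpec <- function(kernel, nfeat, xs, C, gamma, coef0) {
  name <- if (is.list(kernel)) kernel$name else kernel
  if (!name %in% c("linear", "poly2", "poly3", "rbf"))
    stop("kernel must be one of linear, poly2, poly3, rbf")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(xs))
    gamma <- 1 / (nfeat * ifelse(v > 0, v, 1))
  }
  list(name = name,
       degree = switch(name, poly2 = 2, poly3 = 3, 0),
       gamma = gamma, coef0 = coef0, C = C)
}

## kernel matrix K(X, Y) for the four supported kernels
.kernelMatrix <- function(spec, x, y) {
  g <- spec$gamma
  switch(spec$name,
    linear = x %*% t(y),
    poly2 = (g * (x %*% t(y)) + spec$coef0)^2,
    poly3 = (g * (x %*% t(y)) + spec$coef0)^3,
    rbf = {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * (x %*% t(y))
      exp(-g * pmax(d2, 0))
    })
}

#' Fit the kernel-SVM tissue classifier
#'
#' Soft-margin support-vector machine on z-scored retained features with
#' one of four kernels: linear \code{x.y}, polynomial
#' \code{(gamma x.y + coef0)^d} with d = 2 or 3, or RBF
#' \code{exp(-gamma ||x - y||^2)}. Multiclass handling is one-vs-one
#' voting. The dual problems are solved by libsvm; support vectors, dual
#' coefficients and intercepts are extracted into the model so prediction
#' is self-contained.
#'
#' @param table feature data frame with a \code{label} column.
#' @param selection optional \linkS4class{FeatureSelection}.
#' @param kernel \code{"linear"}, \code{"poly2"}, \code{"poly3"} or
#'   \code{"rbf"} (default \code{"poly3"}, the best-performing kernel for
#'   wound tissue).
#' @param C soft-margin cost (default 1).
#' @param gamma kernel scale; default \code{1/(n_features * var(X))} on
#'   the standardized training matrix.
#' @param coef0 polynomial offset (default 1).
#' @param labels class labels overriding \code{table$label}.
#' @return an \linkS4class{SVMModel}.
#' @export
fitSVM <- function(table, selection = NULL, kernel = "poly3", C = 1,
                   gamma = NULL, coef0 = 1, labels = NULL) {
  d <- .designMatrix(table, selection, labels)
  std <- .fitStandardizer(d$x)
  xs <- .applyStandardizer(d$x, std$center, std$scale)
  spec <- .kernelSpec(kernel, ncol(xs), xs, C, gamma, coef0)
  fit <- e1071::svm(
    x = xs, y = d$y, scale = FALSE, cost = spec$C,
    kernel = switch(spec$name, linear = "linear", rbf = "radial",
                    "polynomial"),
    degree = max(spec$degree, 1), gamma = spec$gamma, coef0 = spec$coef0)
  ## libsvm groups support vectors by class in internal label order
  ord <- fit$labels
  new("SVMModel", kernel = spec,
      svs = fit$SV, coefs = as.matrix(fit$coefs), rho = fit$rho,
      nSV = as.integer(fit$nSV),
      center = std$center, scale = std$scale, features = d$features,
      classes = levels(d$y)[ord])
}

## one-vs-one decision values from the stored libsvm pieces:
## pair (i, j) uses column j-1 of class-i support-vector coefficients and
## column i of class-j coefficients, minus the pair intercept
.svmDecision <- function(model, xs) {
  k <- length(model@classes)
  K <- .kernelMatrix(model@kernel, xs, model@svs)
  starts <- cumsum(c(0L, model@nSV))
  block <- function(ci) (starts[ci] + 1):starts[ci + 1]
  dec <- matrix(0, nrow(xs), k * (k - 1) / 2)
  pair <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pair <- pair + 1L
    bi <- block(i); bj <- block(j)
    dec[, pair] <- K[, bi, drop = FALSE] %*% model@coefs[bi, j - 1] +
      K[, bj, drop = FALSE] %*% model@coefs[bj, i] - model@rho[pair]
  }
  dec
}

#' @rdname predict-BayesModel-method
#' @export
setMethod("predict", "SVMModel", function(object, newdata,
                                          type = c("class", "votes")) {
  type <- match.arg(type)
  xs <- .newdataMatrix(object, newdata)
  k <- length(object@classes)
  dec <- .svmDecision(object, xs)
  votes <- matrix(0, nrow(xs), k, dimnames = list(NULL, object@classes))
  pair <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pair <- pair + 1L
    win <- ifelse(dec[, pair] > 0, i, j)
    for (r in seq_len(nrow(xs)))
      votes[r, win[r]] <- votes[r, win[r]] + 1
  }
  ## tie-break in fixed tissue order, not internal libsvm order
  ord <- order(match(object@classes, c(tissueClasses(), object@classes)))
  votes <- votes[, ord, drop = FALSE]
  if (type == "votes") return(votes)
  colnames(votes)[apply(votes, 1, which.max)]
})

## ---------------------------------------------------------------------------
## Portable model serialization (plain JSON)

#' Serialize models to portable JSON
#'
#' Bayes models store their priors and normal marginal parameters; SVM
#' models store the kernel spec, support vectors, dual coefficients and
#' intercepts. Reloaded models predict identically to the originals.
#'
#' @param model a \linkS4class{BayesModel} or \linkS4class{SVMModel}.
#' @param path JSON file path.
#' @return \code{readModelJSON}: the restored model.
#' @export
writeModelJSON <- function(model, path) {
  obj <- if (is(model, "BayesModel")) {
    list(type = "bayes", classes = model@classes, features = model@features,
         priors = model@priors, means = model@means, vars = model@vars,
         center = model@center, scale = model@scale)
  } else if (is(model, "SVMModel")) {
    list(type = "svm", classes = model@classes, features = model@features,
         kernel = model@kernel, svs = model@svs, coefs = model@coefs,
         rho = model@rho, nSV = model@nSV,
         center = model@center, scale = model@scale)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  named <- function(v) stats::setNames(as.numeric(v), o$features)
  if (o$type == "bayes") {
    new("BayesModel",
        priors = stats::setNames(as.numeric(o$priors), o$classes),
        means = matrix(as.numeric(o$means), length(o$classes),
                       dimnames = list(o$classes, o$features)),
        vars = matrix(as.numeric(o$vars), length(o$classes),
                      dimnames = list(o$classes, o$features)),
        center = named(o$center), scale = named(o$scale),
        features = o$features, classes = o$classes)
  } else if (o$type == "svm") {
    new("SVMModel",
        kernel = as.list(o$kernel),
        svs = matrix(as.numeric(as.matrix(o$svs)), nrow(as.matrix(o$svs)),
                     dimnames = list(NULL, o$features)),
        coefs = as.matrix(o$coefs), rho = as.numeric(o$rho),
        nSV = as.integer(o$nSV),
        center = named(o$center), scale = named(o$scale),
        features = o$features, classes = o$classes)
  } else stop("unknown model type in '", path, "'")
}
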