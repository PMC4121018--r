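#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' A validated flat list of the tunable parameters tying the stages
#' together. Round-trips losslessly through a flat key-value YAML file.
#'
#' @param medianWindow odd median-filter window (default 5).
#' @param seRadius structuring-element radius for mask refinement;
#'   \code{NA} means the size-scaled default of \code{\link{refineMask}}.
#' @param quantBins quantization bins (fixed at 256 in this release;
#'   recorded for provenance).
#' @param fThreshold F cutoff for feature retention (default 21).
#' @param kernel SVM kernel name (default \code{"poly3"}).
#' @param C,gamma,coef0 SVM constants (\code{NA} gamma = data-scaled
#'   default).
#' @param trainFrac stratified training fraction for the split protocol.
#' @param protocol \code{"split"} (stratified hold-out) or
#'   \code{"resubstitution"}.
#' @param seed RNG seed controlling the split.
#' @return a named list with class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(medianWindow = 5, seRadius = NA, quantBins = 256,
                           fThreshold = 21, kernel = "poly3", C = 1,
                           gamma = NA, coef0 = 1, trainFrac = 0.7,
                           protocol = c("split", "resubstitution"),
                           seed = 42) {
  protocol <- match.arg(protocol)
  cfg <- list(medianWindow = medianWindow, seRadius = seRadius,
              quantBins = quantBins, fThreshold = fThreshold,
              kernel = kernel, C = C, gamma = gamma, coef0 = coef0,
              trainFrac = trainFrac, protocol = protocol, seed = seed)
  .validateConfig(cfg)
  structure(cfg, class = "pipelineConfig")
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$medianWindow %% 2 == 1, cfg$medianWindow >= 3,
            cfg$quantBins == 256,
            cfg$fThreshold >= 0, cfg$C > 0, cfg$coef0 >= 0,
            cfg$trainFrac > 0, cfg$trainFrac < 1,
            cfg$kernel %in% c("linear", "poly2", "poly3", "rbf"),
            cfg$protocol %in% c("split", "resubstitution"))
  invisible(cfg)
}

#' Read/write a pipeline configuration
#'
#' @param cfg a \code{pipelineConfig}.
#' @param path YAML key-value file.
#' @return \code{readPipelineConfig}: the restored configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

## stratified split by label, deterministic under the config seed
.stratifiedSplit <- function(labels, frac, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- max(2, round(frac * length(idx)))
    nTrain <- min(nTrain, length(idx) - 1)   # keep >= 1 test row
    train[sample(idx, nTrain)] <- TRUE
  }
  train
}

#' Run the end-to-end wound-assessment pipeline
#'
#' Executes median filtering, saturation-channel segmentation with
#' morphological refinement, per-region feature extraction, F-statistic
#' selection, classifier training (naive Bayes plus the configured SVM
#' kernel) and evaluation, logging each stage. When ground-truth wound
#' masks are present, per-image segmentation Dice overlaps are reported.
#' Deterministic under a fixed config seed.
#'
#' @param inputs list of per-image records, each with elements
#'   \code{image} (\linkS4class{RGBImage}), \code{regions} (list of
#'   labeled \linkS4class{TissueRegion}s) and optionally
#'   \code{woundMask} (ground truth); \code{\link{makeBenchmark}} emits
#'   exactly this shape.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, the feature CSV,
#'   selection CSV, refined masks (PNG), evaluation reports (JSON) and a
#'   run manifest are written there.
#' @param verbose print stage log lines.
#' @return list with \code{features} (data frame), \code{selection},
#'   \code{models} (list \code{bayes}, \code{svm}), \code{reports}
#'   (\linkS4class{EvaluationReport} per model), \code{segmentation}
#'   (per-image data frame: threshold, divergence, area, dice) and
#'   \code{manifest}.
#' @export
runPipeline <- function(inputs, config = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
  .validateConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  stage <- "preprocess"
  res <- tryCatch({
    say("[%s] median filter window %d on %d image(s)", stage,
        config$medianWindow, length(inputs))
    filtered <- lapply(inputs, function(rec)
      medianFilterRGB(rec$image, config$medianWindow))

    stage <- "segment"
    seg <- vector("list", length(inputs))
    for (i in seq_along(inputs)) {
      s <- selectThreshold(sChannel(filtered[[i]]),
                           radius = if (is.na(config$seRadius)) NULL
                                    else config$seRadius)
      refined <- refinedMask(s)
      dice <- if (!is.null(inputs[[i]]$woundMask))
        diceCoefficient(refined, inputs[[i]]$woundMask) else NA_real_
      seg[[i]] <- list(result = s, refined = refined, dice = dice)
      say("[%s] %s: threshold %d, divergence %.3f, dice %s", stage,
          imageId(filtered[[i]]), threshold(s), divergence(s),
          ifelse(is.na(dice), "-", sprintf("%.3f", dice)))
    }
    segTable <- data.frame(
      image_id = vapply(filtered, imageId, ""),
      threshold = vapply(seg, function(s) threshold(s$result), 0),
      divergence = vapply(seg, function(s) divergence(s$result), 0),
      area = vapply(seg, function(s) sum(s$refined), 0),
      dice = vapply(seg, function(s) s$dice, 0))

    stage <- "features"
    feats <- do.call(rbind, lapply(seq_along(inputs), function(i)
      extractFeatureTable(filtered[[i]], inputs[[i]]$regions)))
    say("[%s] %d regions x %d features", stage, nrow(feats),
        length(featureManifest()))

    stage <- "select"
    sel <- selectFeaturesF(feats, threshold = config$fThreshold)
    say("[%s] retained %d features (F > %g)", stage,
        length(retainedFeatures(sel)), config$fThreshold)

    stage <- "train"
    train <- if (config$protocol == "split")
      .stratifiedSplit(feats$label, config$trainFrac, config$seed)
    else rep(TRUE, nrow(feats))
    trainTab <- feats[train, , drop = FALSE]
    testTab <- if (config$protocol == "split")
      feats[!train, , drop = FALSE] else feats
    gamma <- if (is.na(config$gamma)) NULL else config$gamma
    models <- list(
      bayes = fitBayes(trainTab, sel),
      svm = fitSVM(trainTab, sel, kernel = config$kernel, C = config$C,
                   gamma = gamma, coef0 = config$coef0))
    say("[%s] protocol %s: %d train / %d test regions", stage,
        config$protocol, nrow(trainTab), nrow(testTab))

    stage <- "evaluate"
    reports <- lapply(models, function(m)
      evaluationReport(true = testTab$label,
                       predicted = predict(m, testTab)))
    for (nm in names(reports))
      say("[%s] %s: macro %.2f%%, kappa %.3f", stage, nm,
          overallAccuracy(reports[[nm]], "macro"),
          kappaStatistic(reports[[nm]]))

    manifest <- list(package = "woundtissue",
                     version = as.character(utils::packageVersion("woundtissue")),
                     config = unclass(config),
                     nImages = length(inputs), nRegions = nrow(feats),
                     protocol = config$protocol, seed = config$seed)
    list(features = feats, selection = sel, models = models,
         reports = reports, segmentation = segTable, manifest = manifest,
         masks = lapply(seg, `[[`, "refined"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outDir)) {
    writeFeatureTable(res$features, file.path(outDir, "features.csv"))
    writeSelectionCSV(res$selection, file.path(outDir, "selection.csv"))
    for (i in seq_along(res$masks))
      writeMaskPNG(res$masks[[i]],
                   file.path(outDir, sprintf("mask_%03d.png", i)))
    for (nm in names(res$reports))
      writeReportJSON(res$reports[[nm]],
                      file.path(outDir, paste0("report_", nm, ".json")))
    utils::write.csv(res$segmentation,
                     file.path(outDir, "segmentation.csv"), row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
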