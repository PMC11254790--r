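#' Scenario configuration
#'
#' The two experimental protocols: \code{"imbalanced"} trains on the data
#' as segmented (no balancing) with stratified 5-fold cross-validation
#' over the 80\% train+validation portion after holding out 20\% for
#' testing; \code{"balanced"} applies SMOTE/down-sampling balancing (see
#' \code{\link{balanceConfig}}) and trains once on a 60:20:20 split.
#'
#' @param scenario \code{"imbalanced"} or \code{"balanced"}.
#' @param split train/validation/test fractions (must sum to 1).
#' @param stratified stratify all splits by subject (default TRUE; a
#'   closed-set identifier needs every class in every partition).
#' @param cvFolds folds for the imbalanced scenario (default 5).
#' @param balance a \code{\link{balanceConfig}} (balanced scenario).
#' @param train a \code{\link{trainConfig}}.
#' @param seed integer seed for splitting.
#' @return a validated config list.
#' @export
scenarioConfig <- function(scenario = c("balanced", "imbalanced"),
                           split = c(0.6, 0.2, 0.2), stratified = TRUE,
                           cvFolds = 5L, balance = balanceConfig(),
                           train = trainConfig(), seed = 1L) {
  stopIf(abs(sum(split) - 1) > 1e-9, "split fractions must sum to 1")
  stopIf(length(split) != 3, "split must give train, val, test fractions")
  stopIf(cvFolds < 2, "cvFolds must be >= 2")
  list(scenario = match.arg(scenario), split = split,
       stratified = isTRUE(stratified), cvFolds = as.integer(cvFolds),
       balance = balance, train = train, seed = as.integer(seed))
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive partition; with stratification, each class is
#' split at the given ratios (within one beat), so every subject appears
#' in every partition. Deterministic per seed.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param ratios train/val/test fractions summing to 1.
#' @param stratified stratify by subject label.
#' @param seed integer seed.
#' @return list with \code{train}, \code{val}, \code{test}
#'   \linkS4class{BeatDataset}s and the index vectors \code{idx}.
#' @export
splitDataset <- function(ds, ratios = c(0.6, 0.2, 0.2), stratified = TRUE,
                         seed = 1L) {
  stopIf(abs(sum(ratios) - 1) > 1e-9, "ratios must sum to 1")
  n <- nBeats(ds)
  assign3 <- function(idx) {
    m <- length(idx)
    nVal <- round(ratios[2] * m)
    nTest <- round(ratios[3] * m)
    nTrain <- m - nVal - nTest
    list(train = idx[seq_len(nTrain)],
         val = idx[nTrain + seq_len(nVal)],
         test = idx[nTrain + nVal + seq_len(nTest)])
  }
  parts <- withSeed(seed, {
    if (stratified) {
      out <- list(train = integer(0), val = integer(0), test = integer(0))
      for (cl in sort(unique(ds@labels))) {
        idx <- which(ds@labels == cl)
        stopIf(length(idx) < 3,
               "class '%s' has %d beats; at least 3 needed to stratify",
               cl, length(idx))
        p <- assign3(sample(idx))
        out <- Map(c, out, p)
      }
      out
    } else {
      assign3(sample.int(n))
    }
  })
  parts <- lapply(parts, sort)
  list(train = subsetBeats(ds, parts$train),
       val = subsetBeats(ds, parts$val),
       test = subsetBeats(ds, parts$test),
       idx = parts)
}

# stratified fold assignment over a dataset; returns fold id per row
foldAssign <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

aggregateReports <- function(reports) {
  vals <- sapply(reports, function(r)
    c(accuracy = r@accuracy, macro_precision = r@macroPrecision,
      macro_sensitivity = r@macroSensitivity, macro_f1 = r@macroF1))
  list(mean = rowMeans(vals),
       sd = apply(vals, 1L, stats::sd))
}

#' Imbalanced-scenario run (5-fold cross-validation)
#'
#' Holds out the test fraction once, partitions the remaining beats into
#' \code{cvFolds} stratified folds, and for each fold trains on the other
#' folds, validates on it, and evaluates on the held-out test split. No
#' balancing is applied. Returns per-fold reports and their aggregate
#' mean and standard deviation.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param cfg a \code{\link{scenarioConfig}}.
#' @param spec optional \linkS4class{ModelSpec}; defaults to the standard
#'   architecture sized to the label set.
#' @return list with \code{folds} (EvalReports), \code{aggregate},
#'   \code{labelOrder} and the config echo.
#' @export
runScenarioImbalanced <- function(ds, cfg = scenarioConfig("imbalanced"),
                                  spec = NULL) {
  ratios <- cfg$split
  testFrac <- ratios[3]
  sp <- splitDataset(ds, c(1 - testFrac, 0, testFrac), cfg$stratified,
                     cfg$seed)
  dev <- sp$train   # 80% train+validation pool
  test <- sp$test
  labelOrd <- sort(unique(ds@labels))
  if (is.null(spec)) spec <- modelSpec(length(labelOrd),
                                       inputLen = ncol(ds@beats))
  folds <- foldAssign(dev@labels, cfg$cvFolds, childSeed(cfg$seed, 7L))
  reports <- vector("list", cfg$cvFolds)
  for (f in seq_len(cfg$cvFolds)) {
    tr <- subsetBeats(dev, which(folds != f))
    va <- subsetBeats(dev, which(folds == f))
    tcfg <- cfg$train
    tcfg$seed <- childSeed(cfg$train$seed, f)
    fit <- trainClassifier(spec, tr, va, tcfg)
    pred <- predictLabels(fit, test, tcfg$normalize)
    reports[[f]] <- evaluatePredictions(test@labels, pred, labelOrd)
  }
  list(scenario = "imbalanced", folds = reports,
       aggregate = aggregateReports(reports),
       labelOrder = labelOrd, config = cfg)
}

#' Balanced-scenario run (SMOTE)
#'
#' With the default \code{train_only} scope: split 60:20:20 first, then
#' balance the training partition only, so synthetic interpolants of
#' validation/test beats can never reach training. With
#' \code{whole_dataset} scope the full dataset is balanced before
#' splitting (the protocol that makes near-perfect scores attainable, at
#' the cost of interpolation leakage across partitions).
#'
#' @inheritParams runScenarioImbalanced
#' @return list with the single \code{report} (EvalReport), the fitted
#'   \code{model}, \code{labelOrder} and the config echo.
#' @export
runScenarioBalanced <- function(ds, cfg = scenarioConfig("balanced"),
                                spec = NULL) {
  labelOrd <- sort(unique(ds@labels))
  if (is.null(spec)) spec <- modelSpec(length(labelOrd),
                                       inputLen = ncol(ds@beats))
  if (cfg$balance$scope == "whole_dataset") {
    ds <- balanceDataset(ds, cfg$balance)
    sp <- splitDataset(ds, cfg$split, cfg$stratified, cfg$seed)
    tr <- sp$train
  } else {
    sp <- splitDataset(ds, cfg$split, cfg$stratified, cfg$seed)
    tr <- balanceDataset(sp$train, cfg$balance)
  }
  fit <- trainClassifier(spec, tr, sp$val, cfg$train)
  pred <- predictLabels(fit, sp$test, cfg$train$normalize)
  report <- evaluatePredictions(sp$test@labels, pred, labelOrd)
  list(scenario = "balanced", report = report, model = fit,
       labelOrder = labelOrd, splits = sp, config = cfg)
}

#' End-to-end pipeline run
#'
#' Full chain on a list of records: preprocess (resample + band-pass),
#' segment (detection + rigid thresholding + interpolation), merge into
#' one beat table, then run the requested scenario. Intermediate
#' artifacts (beats CSV, balanced CSV, report JSON) are persisted when
#' \code{outDir} is given. Subjects whose records yield fewer than the
#' reference RR count are absent from the label set (with a warning from
#' segmentation).
#'
#' @param records list of \linkS4class{EcgRecord}.
#' @param preCfg a \code{\link{preprocessConfig}}.
#' @param segCfg a \code{\link{segmentationConfig}}.
#' @param scnCfg a \code{\link{scenarioConfig}}.
#' @param outDir optional output directory for artifacts.
#' @param quiet suppress stage logging.
#' @return the scenario run result, with the merged \code{beats} dataset
#'   attached.
#' @export
runEndToEnd <- function(records, preCfg = preprocessConfig(),
                        segCfg = segmentationConfig(),
                        scnCfg = scenarioConfig(), outDir = NULL,
                        quiet = FALSE) {
  segs <- lapply(records, function(r)
    segmentRecord(preprocessRecord(r, preCfg), segCfg, quiet = quiet))
  segs <- segs[vapply(segs, nBeats, integer(1)) > 0]
  stopIf(length(segs) == 0, "no record produced any beats")
  beats <- bindBeats(segs)
  if (!quiet)
    logMsg("merged %d beats from %d records (%d subjects)",
           nBeats(beats), length(segs), length(unique(beats@labels)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeBeatsCsv(beats, file.path(outDir, "beats.csv"))
  }
  res <- if (scnCfg$scenario == "imbalanced")
    runScenarioImbalanced(beats, scnCfg)
  else
    runScenarioBalanced(beats, scnCfg)
  res$beats <- beats
  if (!is.null(outDir)) {
    rep <- if (scnCfg$scenario == "imbalanced")
      list(scenario = "imbalanced",
           folds = lapply(res$folds, reportAsList),
           aggregate = res$aggregate)
    else
      c(list(scenario = "balanced"), reportAsList(res$report))
    jsonlite::write_json(rep, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
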