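#' Configuration of a two-step modelling run
#'
#' Collects every tunable of the routine: cross-validation layout,
#' binarization policy, significance screening thresholds, the feature
#' cap of the discrete models, the expression component count, the
#' algorithm roster and the ablation depth.
#'
#' @param nFolds number of cross-validation folds, default 10.
#' @param seed master seed; every stochastic stage (fold assignment,
#'   neural-network initialization, bagging, boosting, inner CV) derives
#'   its own sub-seed from it.
#' @param alpha significance level of the feature association tests,
#'   default 0.05 (Bonferroni-corrected by the per-fold test count).
#' @param minCountGenomic minimum per-state instance count for genomic
#'   features, default 15.
#' @param minCountTissue minimum tissue membership count, default 10.
#' @param featureCap maximum number of non-redundant clustering features,
#'   default 10 (at most 1024 clusters).
#' @param quantiles binarization quantile pair, default `c(0.25, 0.75)`.
#' @param policy `"quartile_exclude_middle"` (default) or
#'   `"quartile_full"`, see [binarizeResponse()].
#' @param nComponents expression principal components, default 7.
#' @param algorithms second-step roster, default all of
#'   [algorithmRegistry()].
#' @param ablation run the ablation studies (default `TRUE`).
#' @param maxRemove maximum number of inputs removed per ablation subset,
#'   default 3.
#' @param minFoldsAblation fold-frequency threshold for reporting,
#'   default 5.
#' @param varEqual pooled-variance t-tests (default) or Welch.
#' @return Classed configuration list.
#' @export
twoStepConfig <- function(nFolds = 10L, seed = 1L, alpha = 0.05,
                          minCountGenomic = 15L, minCountTissue = 10L,
                          featureCap = 10L, quantiles = c(0.25, 0.75),
                          policy = "quartile_exclude_middle",
                          nComponents = 7L,
                          algorithms = algorithmRegistry()$id,
                          ablation = TRUE, maxRemove = 3L,
                          minFoldsAblation = 5L, varEqual = TRUE) {
  bad <- setdiff(algorithms, algorithmRegistry()$id)
  if (length(bad))
    .validationError(sprintf("unknown algorithm(s): %s",
                             paste(bad, collapse = ", ")))
  config <- list(nFolds = as.integer(nFolds), seed = as.integer(seed),
                 alpha = alpha, minCountGenomic = as.integer(minCountGenomic),
                 minCountTissue = as.integer(minCountTissue),
                 featureCap = as.integer(featureCap), quantiles = quantiles,
                 policy = policy, nComponents = as.integer(nComponents),
                 algorithms = algorithms, ablation = isTRUE(ablation),
                 maxRemove = as.integer(maxRemove),
                 minFoldsAblation = as.integer(minFoldsAblation),
                 varEqual = isTRUE(varEqual))
  class(config) <- "twoStepConfig"
  config
}

.discreteLayers <- c("mutation", "cnv", "methylation", "tissue")

# fit all first-step models of one fold; returns models plus train/test
# prediction vectors (pre-binarization, [0,1] scale)
.fitFirstStepFold <- function(mats, layers, trainIds, testIds, aucTrain,
                              yTrain, config) {
  models <- list()
  trP <- list()
  teP <- list()
  for (layer in layers) {
    trainMat <- mats[[layer]][trainIds, , drop = FALSE]
    testMat <- mats[[layer]][testIds, , drop = FALSE]
    if (layer %in% .discreteLayers) {
      minC <- if (layer == "tissue") config$minCountTissue
              else config$minCountGenomic
      fit <- .fitFirstStepDiscrete(trainMat, layer, aucTrain, yTrain,
                                   alpha = config$alpha, minCount = minC,
                                   featureCap = config$featureCap,
                                   varEqual = config$varEqual)
      model <- fit$model
      tr <- predict(model, trainMat)
      te <- predict(model, testMat)
      if (!model@constant && length(unique(tr)) > 1L) {
        model@cutoff <- .chooseCutoff(tr, yTrain)$cutoff
      } else {
        model@constant <- TRUE
      }
    } else if (layer == "pathway") {
      model <- fitPathwayModel(trainMat, yTrain)
      tr <- predict(model, trainMat, type = "normalized")
      te <- predict(model, testMat, type = "normalized")
    } else {
      model <- fitExpressionModel(trainMat, yTrain,
                                  nComponents = config$nComponents)
      tr <- predict(model, trainMat, type = "normalized")
      te <- predict(model, testMat, type = "normalized")
    }
    models[[layer]] <- model
    trP[[layer]] <- tr
    teP[[layer]] <- te
  }
  list(models = models, trainPreds = trP, testPreds = teP)
}

.isModelConstant <- function(model) {
  if (is(model, "ClusterModel") || is(model, "ContinuousFirstStepModel"))
    model@constant
  else TRUE
}

.modelCutoff <- function(model) model@cutoff

#' Run the complete two-step modelling routine for one drug
#'
#' Per cross-validation fold: the response is binarized at the quartile
#' thresholds of the training fold only; the six first-step models are
#' fitted on the training cells; constant first-step outputs are removed;
#' the surviving outputs are integrated by the configured second-step
#' algorithms; and, when enabled, every ablation subset of up to three
#' inputs is refitted. Cross-fold aggregation yields metric tables,
#' importance scores, ablation relative performances and the biomarker
#' stability report.
#'
#' Test cells whose AUC falls strictly between the training-fold
#' thresholds receive predictions but carry no label and are excluded
#' from scoring in that fold.
#'
#' @param dataset an [OmicsDataset-class].
#' @param config a [twoStepConfig()].
#' @return A [TwoStepRun-class].
#' @export
runTwoStep <- function(dataset, config = twoStepConfig()) {
  stopifnot(is(dataset, "OmicsDataset"))
  auc <- response(dataset)
  layers <- presentLayers(dataset)
  thrG <- computeQuartileThresholds(auc, config$quantiles)
  labG <- binarizeResponse(auc, thrG$q1, thrG$q3, config$policy)
  partition <- makeCVPartition(labG, config$nFolds, config$seed)
  modelled <- names(labG)[!is.na(labG)]
  mats <- lapply(stats::setNames(layers, layers),
                 function(l) layerMatrix(dataset, l))
  algs <- config$algorithms
  scoreAlg <- stats::setNames(algorithmRegistry()$usesScore,
                              algorithmRegistry()$id)

  predRows <- list(); metricRows <- list(); rocRows <- list()
  impRows <- list(); ablRows <- list(); featTables <- vector("list",
                                                            config$nFolds)
  foldInfo <- vector("list", config$nFolds)
  firstStepModels <- vector("list", config$nFolds)

  addMetrics <- function(fold, step, model, set, pred, truth) {
    m <- computeMetrics(pred, truth)
    metricRows[[length(metricRows) + 1L]] <<- data.frame(
      fold = fold, step = step, model = model, set = set, t(m),
      stringsAsFactors = FALSE)
  }
  addRoc <- function(fold, step, model, set, score, truth) {
    rocRows[[length(rocRows) + 1L]] <<- data.frame(
      fold = fold, step = step, model = model, set = set,
      rocAuc = computeRocAuc(score, truth), stringsAsFactors = FALSE)
  }
  addPreds <- function(fold, step, model, set, score, class, cells) {
    predRows[[length(predRows) + 1L]] <<- data.frame(
      fold = fold, step = step, model = model, set = set, cellLine = cells,
      score = unname(score), class = unname(class),
      stringsAsFactors = FALSE)
  }

  for (f in seq_len(config$nFolds)) {
    testIds <- testFoldIds(partition, f)
    # thresholds are recomputed on the response of every non-test cell
    # line (the full training panel, not only the globally modelled set)
    trainAll <- setdiff(names(auc), testIds)
    thr <- computeQuartileThresholds(auc[trainAll], config$quantiles)
    trLabAll <- binarizeResponse(auc[trainAll], thr$q1, thr$q3,
                                 config$policy)
    trainIds <- trainAll[!is.na(trLabAll)]
    yTrain <- trLabAll[trainIds]
    if (length(unique(yTrain)) < 2L)
      .validationError(sprintf("fold %d: single-class training labels", f))
    teLab <- binarizeResponse(auc[testIds], thr$q1, thr$q3, config$policy)
    scored <- !is.na(teLab)

    fs <- .fitFirstStepFold(mats, layers, trainIds, testIds, auc[trainIds],
                            yTrain, config)
    firstStepModels[[f]] <- fs$models

    # per-fold significant-feature table (discrete layers)
    ft <- list()
    for (layer in intersect(.discreteLayers, layers)) {
      rel <- fs$models[[layer]]@relevant
      if (nrow(rel))
        ft[[layer]] <- data.frame(fold = f, dataType = layer, rel,
                                  stringsAsFactors = FALSE)
    }
    featTables[[f]] <- if (length(ft)) do.call(rbind, ft) else NULL

    # first-step reporting
    for (layer in layers) {
      model <- fs$models[[layer]]
      constant <- .isModelConstant(model)
      tr <- fs$trainPreds[[layer]]
      te <- fs$testPreds[[layer]]
      cut <- .modelCutoff(model)
      trC <- if (constant) rep(NA_real_, length(tr))
             else as.numeric(tr >= cut)
      teC <- if (constant) rep(NA_real_, length(te))
             else as.numeric(te >= cut)
      addPreds(f, "first", layer, "train", tr, trC, trainIds)
      addPreds(f, "first", layer, "test", te, teC, testIds)
      if (!constant) {
        addMetrics(f, "first", layer, "train", trC, yTrain)
        addMetrics(f, "first", layer, "test", teC[scored], teLab[scored])
        addRoc(f, "first", layer, "train", tr, yTrain)
        addRoc(f, "first", layer, "test", te[scored], teLab[scored])
      }
    }

    inputs <- assembleInputs(fs$trainPreds, fs$testPreds)
    slots <- inputs$slots

    for (ai in seq_along(algs)) {
      alg <- algs[ai]
      seedA <- .deriveSeed(config$seed, f, 100L + ai)
      model <- fitSecondStep(inputs$train, yTrain, alg, seedA)
      trC <- predict(model, inputs$train, type = "class")
      teC <- predict(model, inputs$test, type = "class")
      useScore <- scoreAlg[[alg]] && model@constant == FALSE &&
        model@converged
      trS <- if (useScore) predict(model, inputs$train, type = "normalized")
             else rep(NA_real_, length(trC))
      teS <- if (useScore) predict(model, inputs$test, type = "normalized")
             else rep(NA_real_, length(teC))
      addPreds(f, "second", alg, "train", trS, trC, trainIds)
      addPreds(f, "second", alg, "test", teS, teC, testIds)
      addMetrics(f, "second", alg, "train", trC, yTrain)
      addMetrics(f, "second", alg, "test", teC[scored], teLab[scored])
      if (scoreAlg[[alg]]) {
        addRoc(f, "second", alg, "train", trS, yTrain)
        addRoc(f, "second", alg, "test", teS[scored], teLab[scored])
      }
      imp <- extractImportances(model)
      if (!is.null(imp))
        impRows[[length(impRows) + 1L]] <- data.frame(
          fold = f, algorithm = alg, slot = names(imp),
          importance = unname(imp), stringsAsFactors = FALSE)

      if (config$ablation) {
        subsets <- enumerateAblationSubsets(slots, config$maxRemove)
        for (si in seq_along(subsets)) {
          rem <- subsets[[si]]
          keep <- setdiff(slots, rem)
          xTr <- inputs$train[, keep, drop = FALSE]
          xTe <- inputs$test[, keep, drop = FALSE]
          seedS <- .deriveSeed(config$seed, f, 100L + ai, si)
          am <- fitSecondStep(xTr, yTrain, alg, seedS)
          if (scoreAlg[[alg]] && am@converged && !am@constant) {
            sTr <- predict(am, xTr, type = "normalized")
            sTe <- predict(am, xTe, type = "normalized")
            mTr <- computeRocAuc(sTr, yTrain)
            mTe <- computeRocAuc(sTe[scored], teLab[scored])
            metricName <- "rocAuc"
          } else {
            cTr <- predict(am, xTr, type = "class")
            cTe <- predict(am, xTe, type = "class")
            mTr <- mean(cTr == yTrain)
            mTe <- mean(cTe[scored] == teLab[scored])
            metricName <- "accuracy"
          }
          ablRows[[length(ablRows) + 1L]] <- data.frame(
            fold = f, algorithm = alg, subset = .subsetKey(rem),
            size = length(rem), metricName = metricName,
            metricTrain = mTr, metricTest = mTe, stringsAsFactors = FALSE)
        }
      }
    }
    foldInfo[[f]] <- list(fold = f, q1 = thr$q1, q3 = thr$q3,
                          nTrain = length(trainIds),
                          nTest = length(testIds),
                          nTestScored = sum(scored), slots = slots)
  }

  metrics <- do.call(rbind, metricRows)
  roc <- do.call(rbind, rocRows)
  preds <- do.call(rbind, predRows)
  importance <- if (length(impRows)) do.call(rbind, impRows) else
    data.frame(fold = integer(), algorithm = character(),
               slot = character(), importance = numeric(),
               stringsAsFactors = FALSE)

  ablation <- NULL
  if (config$ablation && length(ablRows)) {
    raw <- do.call(rbind, ablRows)
    ablation <- .aggregateAblation(raw, roc, metrics, config)
  }

  # per-fold mean relative importance of each first-step slot across
  # weight-producing algorithms, feeding the stability report
  impBySlot <- if (nrow(importance)) {
    agg <- stats::aggregate(importance ~ fold + slot, importance, mean)
    names(agg) <- c("fold", "slot", "importance")
    agg
  } else {
    data.frame(fold = integer(), slot = character(),
               importance = numeric(), stringsAsFactors = FALSE)
  }
  stability <- aggregateStability(featTables, impBySlot,
                                  nFolds = config$nFolds)

  new("TwoStepRun", drugLabel = drugLabel(dataset),
      config = unclass(config), partition = partition,
      results = list(
        metrics = metrics, rocAuc = roc, predictions = preds,
        importance = importance, ablation = ablation,
        ablationPerFold = if (config$ablation && length(ablRows))
          do.call(rbind, ablRows) else NULL,
        stability = stability, featureTables = featTables,
        firstStepModels = firstStepModels, foldInfo = foldInfo,
        globalThresholds = thrG, globalLabels = labG,
        measured = data.frame(cellLine = names(auc), auc = unname(auc),
                              globalLabel = unname(labG),
                              fold = unname(partition@assignments[names(auc)]),
                              stringsAsFactors = FALSE)))
}

# mean-across-folds metric, normalized by the full model's mean metric
.aggregateAblation <- function(raw, roc, metrics, config) {
  scoreAlg <- stats::setNames(algorithmRegistry()$usesScore,
                              algorithmRegistry()$id)
  fullMean <- function(alg) {
    if (scoreAlg[[alg]]) {
      v <- roc$rocAuc[roc$step == "second" & roc$model == alg &
                      roc$set == "test"]
    } else {
      v <- metrics$accuracy[metrics$step == "second" &
                            metrics$model == alg & metrics$set == "test"]
    }
    mean(v, na.rm = TRUE)
  }
  combos <- unique(raw[, c("algorithm", "subset", "size")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    rows <- raw[raw$algorithm == combos$algorithm[i] &
                raw$subset == combos$subset[i], , drop = FALSE]
    meanTest <- mean(rows$metricTest, na.rm = TRUE)
    data.frame(algorithm = combos$algorithm[i], subset = combos$subset[i],
               size = combos$size[i], metricName = rows$metricName[1L],
               foldCount = nrow(rows),
               meanTrain = mean(rows$metricTrain, na.rm = TRUE),
               meanTest = meanTest,
               relPerformance = relativePerformance(
                 meanTest, fullMean(combos$algorithm[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # canonical ordering: registry order, then size, then slot order
  slotRank <- stats::setNames(seq_along(canonicalLayers()),
                              canonicalLayers())
  subsetRank <- vapply(strsplit(out$subset, "+", fixed = TRUE),
                       function(s) sum(slotRank[s] * 10^(3 - seq_along(s))),
                       numeric(1L))
  out$subsetOrder <- out$size * 1e6 + subsetRank
  algRank <- match(out$algorithm, algorithmRegistry()$id)
  out[order(algRank, out$size, subsetRank), , drop = FALSE]
}
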