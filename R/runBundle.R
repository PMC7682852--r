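#' @rdname TwoStepRun-class
#' @description per-fold evaluation metrics (accuracy,
#'   precision, recall, F1, FDR) of all first- and second-step models.
#' @param x,object,bundle a `TwoStepRun`.
#' @param set `"test"`, `"train"` or `"both"`.
#' @export
metricsTable <- function(x, set = c("both", "test", "train")) {
  set <- match.arg(set)
  m <- x@results$metrics
  if (set != "both") m <- m[m$set == set, , drop = FALSE]
  m
}

#' @rdname TwoStepRun-class
#' @description per-fold ROC-AUCs of all score-producing
#'   models (the naive Bayes classifier has none).
#' @export
rocAucTable <- function(x) x@results$rocAuc

#' @rdname TwoStepRun-class
#' @description pre- and post-binarization prediction vectors
#'   of every model on the training and test set of every fold.
#' @export
predictionsTable <- function(x) x@results$predictions

#' @rdname TwoStepRun-class
#' @description per-fold input weights/importance scores of
#'   the weight-producing second-step algorithms (max-1 scaled).
#' @export
importanceTable <- function(x) x@results$importance

#' @rdname TwoStepRun-class
#' @description aggregated ablation records: per algorithm and
#'   removed-input subset the fold count, mean train/test metric and the
#'   relative performance versus the full model (ROC-AUC, accuracy for
#'   naive Bayes). Apply [filterByFoldFrequency()] before analysis.
#' @export
ablationTable <- function(x) x@results$ablation

#' @rdname TwoStepRun-class
#' @description cross-fold biomarker stability report, see
#'   [aggregateStability()].
#' @export
stabilityTable <- function(x) x@results$stability

#' @rdname TwoStepRun-class
#' @description per-fold significant-feature tables of the
#'   discrete first-step models (redundant features included).
#' @export
significantFeatureTable <- function(x) {
  ft <- x@results$featureTables
  ft <- ft[!vapply(ft, is.null, logical(1L))]
  if (!length(ft))
    return(data.frame(fold = integer(), dataType = character(),
                      feature = character(), p = numeric(),
                      nPresent = integer(), direction = character(),
                      redundant = logical(), stringsAsFactors = FALSE))
  do.call(rbind, ft)
}

#' @rdname TwoStepRun-class
#' @description measured response (raw AUC, global binarized
#'   label, fold assignment) per cell line.
#' @export
measuredResponseTable <- function(x) x@results$measured

setMethod("show", "TwoStepRun", function(object) {
  cfg <- object@config
  cat(sprintf("TwoStepRun for drug '%s': %d folds, seed %d\n",
              object@drugLabel, cfg$nFolds, cfg$seed))
  cat(sprintf("  modelled cell lines: %d (of %d)\n",
              sum(!is.na(object@partition@assignments)),
              length(object@partition@assignments)))
  roc <- rocAucTable(object)
  second <- roc[roc$step == "second" & roc$set == "test", , drop = FALSE]
  if (nrow(second)) {
    mu <- tapply(second$rocAuc, second$model, mean, na.rm = TRUE)
    best <- names(mu)[which.max(mu)]
    cat(sprintf("  best second-step test ROC-AUC: %.3f (%s)\n",
                max(mu, na.rm = TRUE), best))
  }
  st <- stabilityTable(object)
  cat(sprintf("  stable discrete features (>= 7/%d folds): %d\n",
              cfg$nFolds, sum(st$stable)))
})

#' Summarize a two-step run
#'
#' Per-algorithm mean and SD of the train/test ROC-AUC (accuracy for the
#' naive Bayes classifier), the overfitting margin (train minus test),
#' the best-performing algorithm and the stable features with their
#' effect directions.
#'
#' @param bundle a [TwoStepRun-class].
#' @param quiet suppress printing.
#' @return Invisibly, a list with `algorithms` (data.frame) and
#'   `stableFeatures` (data.frame).
#' @export
summarizeRun <- function(bundle, quiet = FALSE) {
  roc <- rocAucTable(bundle)
  metrics <- metricsTable(bundle)
  algs <- intersect(algorithmRegistry()$id, bundle@config$algorithms)
  scoreAlg <- stats::setNames(algorithmRegistry()$usesScore,
                              algorithmRegistry()$id)
  rows <- lapply(algs, function(a) {
    if (scoreAlg[[a]]) {
      tr <- roc$rocAuc[roc$model == a & roc$set == "train"]
      te <- roc$rocAuc[roc$model == a & roc$set == "test"]
      metric <- "rocAuc"
    } else {
      tr <- metrics$accuracy[metrics$model == a & metrics$set == "train"]
      te <- metrics$accuracy[metrics$model == a & metrics$set == "test"]
      metric <- "accuracy"
    }
    data.frame(algorithm = a, metric = metric,
               meanTrain = mean(tr, na.rm = TRUE),
               sdTrain = stats::sd(tr[is.finite(tr)]),
               meanTest = mean(te, na.rm = TRUE),
               sdTest = stats::sd(te[is.finite(te)]),
               overfitMargin = mean(tr, na.rm = TRUE) -
                 mean(te, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  algTable <- do.call(rbind, rows)
  st <- stabilityTable(bundle)
  stable <- st[st$stable, , drop = FALSE]
  if (!quiet) {
    cat(sprintf("Two-step run for drug '%s'\n", bundle@drugLabel))
    best <- algTable[which.max(algTable$meanTest), ]
    for (i in seq_len(nrow(algTable)))
      cat(sprintf("  %-12s %s train %.3f +/- %.3f  test %.3f +/- %.3f  (overfit %+0.3f)\n",
                  algTable$algorithm[i], algTable$metric[i],
                  algTable$meanTrain[i], algTable$sdTrain[i],
                  algTable$meanTest[i], algTable$sdTest[i],
                  algTable$overfitMargin[i]))
    cat(sprintf("best algorithm: %s (mean test %s %.3f)\n", best$algorithm,
                best$metric, best$meanTest))
    if (nrow(stable)) {
      cat("stable features:\n")
      for (i in seq_len(nrow(stable)))
        cat(sprintf("  %-12s %-14s %d/%d folds  %s\n", stable$dataType[i],
                    stable$feature[i], stable$foldHits[i],
                    bundle@config$nFolds, stable$direction[i]))
    } else cat("stable features: none\n")
  }
  invisible(list(algorithms = algTable, stableFeatures = stable))
}

#' Write the result bundle of a run as delimited tables
#'
#' Emits the twelve output groups of the routine as TSV files - first-
#' and second-step model descriptions, pre- and post-binarization
#' predictions on training and test sets, raw and binarized measured
#' response, train/test metric tables, ROC-AUCs, significant-feature
#' sets, first-step importances, ablation results and the CV partition -
#' plus a machine-readable key-value run summary.
#'
#' @param bundle a [TwoStepRun-class].
#' @param dir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
writeRunBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character()

  fs <- lapply(seq_along(bundle@results$firstStepModels), function(f) {
    models <- bundle@results$firstStepModels[[f]]
    do.call(rbind, lapply(names(models), function(layer) {
      m <- models[[layer]]
      data.frame(fold = f, dataType = layer,
                 constant = .isModelConstant(m),
                 nFeatures = if (is(m, "ClusterModel"))
                   length(m@nonredundant) else m@nComponents,
                 nClusters = if (is(m, "ClusterModel")) nrow(m@clusters)
                   else NA_integer_,
                 cutoff = .modelCutoff(m), stringsAsFactors = FALSE)
    }))
  })
  paths["first_step_models"] <- wt(do.call(rbind, fs),
                                   "first_step_models.tsv")

  clusters <- list()
  for (f in seq_along(bundle@results$firstStepModels)) {
    for (layer in names(bundle@results$firstStepModels[[f]])) {
      m <- bundle@results$firstStepModels[[f]][[layer]]
      if (!is(m, "ClusterModel") || !nrow(m@clusters)) next
      cl <- m@clusters
      states <- if (ncol(m@states))
        apply(m@states, 1L, function(r)
          paste(sprintf("%s=%g", colnames(m@states), r), collapse = ";"))
      else rep("", nrow(cl))
      clusters[[length(clusters) + 1L]] <- data.frame(
        fold = f, dataType = layer, cl, states = unname(states),
        stringsAsFactors = FALSE)
    }
  }
  if (length(clusters))
    paths["first_step_clusters"] <- wt(do.call(rbind, clusters),
                                       "first_step_clusters.tsv")

  second <- unique(bundle@results$metrics[
    bundle@results$metrics$step == "second", c("fold", "model")])
  names(second) <- c("fold", "algorithm")
  paths["second_step_models"] <- wt(second, "second_step_models.tsv")

  preds <- predictionsTable(bundle)
  paths["predictions_train"] <- wt(preds[preds$set == "train", ],
                                   "predictions_train.tsv")
  paths["predictions_test"] <- wt(preds[preds$set == "test", ],
                                  "predictions_test.tsv")
  paths["measured_response"] <- wt(measuredResponseTable(bundle),
                                   "measured_response.tsv")
  paths["metrics_train"] <- wt(metricsTable(bundle, "train"),
                               "metrics_train.tsv")
  paths["metrics_test"] <- wt(metricsTable(bundle, "test"),
                              "metrics_test.tsv")
  paths["roc_auc"] <- wt(rocAucTable(bundle), "roc_auc.tsv")
  paths["significant_features"] <- wt(significantFeatureTable(bundle),
                                      "significant_features.tsv")
  paths["importances"] <- wt(importanceTable(bundle), "importances.tsv")
  if (!is.null(ablationTable(bundle)))
    paths["ablation"] <- wt(ablationTable(bundle), "ablation.tsv")
  part <- data.frame(cellLine = names(bundle@partition@assignments),
                     fold = unname(bundle@partition@assignments),
                     stringsAsFactors = FALSE)
  paths["cv_partition"] <- wt(part, "cv_partition.tsv")
  paths["stability"] <- wt(stabilityTable(bundle), "stability.tsv")

  smry <- summarizeRun(bundle, quiet = TRUE)
  best <- smry$algorithms[which.max(smry$algorithms$meanTest), ]
  cfg <- bundle@config
  kv <- c(drug = bundle@drugLabel,
          n_cell_lines = nrow(measuredResponseTable(bundle)),
          n_modelled = sum(!is.na(bundle@partition@assignments)),
          n_folds = cfg$nFolds, seed = cfg$seed, alpha = cfg$alpha,
          policy = cfg$policy, feature_cap = cfg$featureCap,
          n_components = cfg$nComponents,
          best_algorithm = best$algorithm,
          best_mean_test = sprintf("%.6f", best$meanTest),
          n_stable_features = sum(stabilityTable(bundle)$stable))
  writeLines(paste(names(kv), unname(kv), sep = "\t"),
             file.path(dir, "run_summary.txt"))
  paths["run_summary"] <- file.path(dir, "run_summary.txt")
  invisible(paths)
}
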