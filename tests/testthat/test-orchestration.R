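# scaled-down configuration used for the orchestration unit tests
tinyConfig <- function(...) {
  twoStepConfig(nFolds = 3L, seed = 11L, ablation = FALSE, ...)
}

tinySim <- function(seed = 2) {
  generateDataset(syntheticSpec(
    nCells = 150L, nGenes = c(mutation = 60L, cnv = 40L, methylation = 40L),
    nExprGenes = 40L, seed = seed, drivers = list(
      list(layer = "mutation", effect = 2, direction = "sensitivity",
           carrierFrac = 0.3))))
}

test_that("a run produces the full per-fold output contract", {
  sim <- tinySim()
  b <- runTwoStep(sim$dataset, tinyConfig())
  expect_s4_class(b, "TwoStepRun")

  # per-fold quantities carry one row per fold for every fitted model
  roc <- rocAucTable(b)
  second <- roc[roc$step == "second" & roc$set == "test", ]
  expect_equal(as.integer(table(second$model)),
               rep(3L, length(unique(second$model))))
  expect_length(unique(second$model), 12)  # all score algorithms, nb has none

  met <- metricsTable(b, "test")
  expect_true(all(table(met$model[met$step == "second"]) == 3))
  expect_true(all(c("accuracy", "precision", "recall", "f1", "fdr") %in%
                  colnames(met)))

  # first-step results appear in canonical order
  fsModels <- names(b@results$firstStepModels[[1]])
  expect_identical(fsModels, canonicalLayers())

  # metric consistency on reported rows
  ok <- !is.na(met$precision) & !is.na(met$fdr)
  expect_equal(met$precision[ok] + met$fdr[ok], rep(1, sum(ok)),
               tolerance = 1e-12)
})

test_that("test predictions cover each modelled cell line exactly once", {
  sim <- tinySim(seed = 4)
  b <- runTwoStep(sim$dataset, tinyConfig())
  preds <- predictionsTable(b)
  modelled <- names(b@partition@assignments)[
    !is.na(b@partition@assignments)]
  for (model in unique(preds$model)) {
    rows <- preds[preds$set == "test" & preds$model == model, ]
    expect_identical(sort(rows$cellLine), sort(modelled))
  }
})

test_that("runs are deterministic given dataset, config and seed", {
  sim <- tinySim(seed = 6)
  cfg <- twoStepConfig(nFolds = 3L, seed = 21L, ablation = TRUE)
  b1 <- runTwoStep(sim$dataset, cfg)
  b2 <- runTwoStep(sim$dataset, cfg)
  expect_identical(b1@results$metrics, b2@results$metrics)
  expect_identical(b1@results$rocAuc, b2@results$rocAuc)
  expect_identical(b1@results$predictions, b2@results$predictions)
  expect_identical(b1@results$importance, b2@results$importance)
  expect_identical(b1@results$ablation, b2@results$ablation)
  expect_identical(b1@partition, b2@partition)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeRunBundle(b1, d1)
  writeRunBundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("bundle files cover the twelve output groups", {
  sim <- tinySim(seed = 8)
  b <- runTwoStep(sim$dataset, twoStepConfig(nFolds = 3L, seed = 1L,
                                             ablation = TRUE))
  dir <- withr::local_tempdir()
  paths <- writeRunBundle(b, dir)
  needed <- c("first_step_models", "second_step_models",
              "predictions_train", "predictions_test", "measured_response",
              "metrics_train", "metrics_test", "roc_auc",
              "significant_features", "importances", "ablation",
              "cv_partition", "run_summary")
  expect_true(all(needed %in% names(paths)))
  expect_true(all(file.exists(paths)))
  part <- read.delim(paths[["cv_partition"]])
  expect_equal(nrow(part), 150)
})

test_that("reduced layer sets are tolerated end to end", {
  sim <- tinySim(seed = 10)
  ds <- sim$dataset
  mats <- list(mutation = ds@layers$mutation, pathway = ds@layers$pathway)
  small <- alignDataset(mats, response(ds), drug = "reduced",
                        verbose = FALSE)
  b <- runTwoStep(small, tinyConfig(algorithms = c("nb", "logit",
                                                   "lm_ridge")))
  expect_identical(names(b@results$firstStepModels[[1]]),
                   c("mutation", "pathway"))
  roc <- rocAucTable(b)
  expect_true(all(unique(roc$model[roc$step == "second"]) %in%
                  c("logit", "lm_ridge")))
})

test_that("summaries report overfitting margins and the best algorithm", {
  sim <- tinySim(seed = 12)
  b <- runTwoStep(sim$dataset, tinyConfig())
  s <- summarizeRun(b, quiet = TRUE)
  expect_equal(nrow(s$algorithms), 13)
  expect_true(all(is.finite(s$algorithms$meanTest)))
  expect_identical(
    s$algorithms$overfitMargin,
    s$algorithms$meanTrain - s$algorithms$meanTest)
  out <- capture.output(summarizeRun(b))
  expect_true(any(grepl("best algorithm", out)))
})

test_that("fold models never see test-fold data", {
  sim <- tinySim(seed = 14)
  ds <- sim$dataset
  cfg <- tinyConfig()
  auc <- response(ds)
  thrG <- computeQuartileThresholds(auc)
  labG <- binarizeResponse(auc, thrG$q1, thrG$q3)
  part <- makeCVPartition(labG, cfg$nFolds, cfg$seed)
  testIds <- testFoldIds(part, 1)
  trainAll <- setdiff(names(auc), testIds)
  thr <- computeQuartileThresholds(auc[trainAll])
  lab <- binarizeResponse(auc[trainAll], thr$q1, thr$q3)
  trainIds <- trainAll[!is.na(lab)]
  mats <- lapply(stats::setNames(presentLayers(ds), presentLayers(ds)),
                 function(l) layerMatrix(ds, l))
  fit1 <- twoStepOmics:::.fitFirstStepFold(
    mats, presentLayers(ds), trainIds, testIds, auc[trainIds],
    lab[trainIds], cfg)

  # perturb every test-fold row in every layer: fitted models unchanged
  matsPert <- mats
  for (l in names(matsPert)) {
    pert <- matsPert[[l]]
    if (l %in% c("pathway", "expression")) {
      pert[testIds, ] <- pert[testIds, ] + 100
    } else if (l == "tissue") {
      pert[testIds, ] <- pert[testIds, c(2:ncol(pert), 1)]
    } else {
      pert[testIds, ] <- 1 - abs(pert[testIds, ])
    }
    matsPert[[l]] <- pert
  }
  fit2 <- twoStepOmics:::.fitFirstStepFold(
    matsPert, presentLayers(ds), trainIds, testIds, auc[trainIds],
    lab[trainIds], cfg)
  expect_identical(fit1$models, fit2$models)
  expect_identical(fit1$trainPreds, fit2$trainPreds)
  # thresholds likewise ignore perturbed test responses
  aucPert <- auc
  aucPert[testIds] <- aucPert[testIds] + 5
  thrPert <- computeQuartileThresholds(aucPert[trainAll])
  expect_identical(thr, thrPert)
})
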