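smallSpec <- function(seed = 1, drivers = list(), ...) {
  syntheticSpec(nCells = 200L,
                nGenes = c(mutation = 80L, cnv = 50L, methylation = 50L),
                nExprGenes = 40L, seed = seed, drivers = drivers, ...)
}

test_that("generation is deterministic and satisfies layer invariants", {
  a <- generateDataset(smallSpec(seed = 5))
  b <- generateDataset(smallSpec(seed = 5))
  expect_identical(a, b)
  c <- generateDataset(smallSpec(seed = 6))
  expect_false(identical(response(a$dataset), response(c$dataset)))

  ds <- a$dataset
  expect_identical(presentLayers(ds), canonicalLayers())
  expect_true(all(layerMatrix(ds, "mutation") %in% c(0, 1)))
  expect_true(all(layerMatrix(ds, "cnv") %in% c(-1, 0, 1)))
  expect_true(all(rowSums(layerMatrix(ds, "tissue")) == 1))
  expect_equal(ncol(layerMatrix(ds, "pathway")), 11)
  expect_true(validObject(ds))
})

test_that("the null world has no planted structure and a 50% modelled split", {
  sim <- generateDataset(smallSpec(seed = 9))
  expect_equal(nrow(sim$truth), 0)
  auc <- response(sim$dataset)
  thr <- computeQuartileThresholds(auc)
  lab <- binarizeResponse(auc, thr$q1, thr$q3)
  expect_equal(sum(!is.na(lab)) / length(lab), 0.5, tolerance = 0.02)
  expect_equal(mean(lab, na.rm = TRUE), 0.5, tolerance = 0.02)
})

test_that("planted drivers shift the response as specified", {
  eff <- 2
  sim <- generateDataset(smallSpec(seed = 3, drivers = list(
    list(layer = "mutation", effect = eff, direction = "sensitivity",
         carrierFrac = 0.3))))
  ds <- sim$dataset
  carrier <- layerMatrix(ds, "mutation")[, sim$truth$feature[1]] == 1
  auc <- response(ds)
  gap <- mean(auc[!carrier]) - mean(auc[carrier])
  expect_equal(gap / 0.1, eff, tolerance = 0.35)  # noiseSd = 0.1

  res <- generateDataset(smallSpec(seed = 3, drivers = list(
    list(layer = "tissue", effect = 1.5, direction = "resistance",
         tissue = 1))))
  tis <- layerMatrix(res$dataset, "tissue")[, "tissue01"] == 1
  expect_gt(mean(response(res$dataset)[tis]),
            mean(response(res$dataset)[!tis]))
})

test_that("undetectably rare drivers trigger a warning", {
  expect_warning(generateDataset(smallSpec(seed = 2, drivers = list(
    list(layer = "mutation", effect = 2, direction = "sensitivity",
         carrierFrac = 0.02)))), "screening threshold")
})

test_that("detection power is non-decreasing in the planted effect size", {
  effects <- c(0.3, 1, 2.5)
  power <- vapply(effects, function(eff) {
    hits <- 0
    for (r in 1:40) {
      sim <- suppressWarnings(generateDataset(
        smallSpec(seed = 1000 + r, drivers = list(
          list(layer = "mutation", effect = eff,
               direction = "sensitivity", carrierFrac = 0.3)))))
      ds <- sim$dataset
      auc <- response(ds)
      thr <- computeQuartileThresholds(auc)
      lab <- binarizeResponse(auc, thr$q1, thr$q3)
      tr <- names(lab)[!is.na(lab)]
      fit <- twoStepOmics:::.fitFirstStepDiscrete(
        layerMatrix(ds, "mutation")[tr, ], "mutation", auc[tr], lab[tr])
      hits <- hits + (sim$truth$feature[1] %in% fit$model@relevant$feature)
    }
    hits / 40
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], 0.9)
})

test_that("duplicate driver columns exercise redundancy pruning", {
  sim <- generateDataset(smallSpec(seed = 4, drivers = list(
    list(layer = "mutation", effect = 2.5, direction = "sensitivity",
         carrierFrac = 0.35)), duplicateDrivers = 1L))
  ds <- sim$dataset
  mut <- layerMatrix(ds, "mutation")
  dupName <- grep("_dup", colnames(mut), value = TRUE)
  expect_length(dupName, 1)
  expect_identical(unname(mut[, dupName]),
                   unname(mut[, sim$truth$feature[1]]))
  auc <- response(ds)
  thr <- computeQuartileThresholds(auc)
  lab <- binarizeResponse(auc, thr$q1, thr$q3)
  tr <- names(lab)[!is.na(lab)]
  fit <- twoStepOmics:::.fitFirstStepDiscrete(mut[tr, ], "mutation",
                                              auc[tr], lab[tr])
  rel <- fit$model@relevant
  expect_true(all(c(sim$truth$feature[1], dupName) %in% rel$feature))
  expect_equal(sum(rel$redundant), 1)
  expect_length(fit$model@redundancyMap, 1)
})

test_that("fixture bundles round-trip through the file readers", {
  sim <- generateDataset(smallSpec(seed = 8))
  dir <- withr::local_tempdir()
  paths <- writeDatasetBundle(sim, dir)
  mats <- list(
    mutation = readFeatureMatrix(paths[["mutation"]], "binary"),
    cnv = readFeatureMatrix(paths[["cnv"]], "ternary"),
    methylation = readFeatureMatrix(paths[["methylation"]], "binary"),
    tissue = readFeatureMatrix(paths[["tissue"]], "onehot"),
    pathway = readFeatureMatrix(paths[["pathway"]], "continuous"),
    expression = readFeatureMatrix(paths[["expression"]], "continuous"))
  resp <- readResponseTable(paths[["response"]])
  back <- alignDataset(mats, resp, drug = 1, verbose = FALSE)
  expect_identical(response(back), response(sim$dataset))
  expect_identical(layerMatrix(back, "expression"),
                   layerMatrix(sim$dataset, "expression"))
})
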