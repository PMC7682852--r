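makeInputs <- function(n = 60, informative = "mutation", seed = 3) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    slots <- canonicalLayers()
    x <- sapply(slots, function(s) runif(n))
    x[, informative] <- y * 0.8 + runif(n) * 0.2
    rownames(x) <- sprintf("C%02d", 1:n)
    list(x = x, y = y)
  })
}

test_that("constant first-step outputs are removed before integration", {
  tr <- list(mutation = c(0.2, 0.8, 0.4), cnv = rep(0.5, 3),
             methylation = NULL, tissue = c(0.1, 0.1, 0.2),
             pathway = c(0.3, 0.4, 0.5), expression = c(0.9, 0.2, 0.4))
  te <- lapply(tr, function(v) if (is.null(v)) NULL else rev(v))
  inp <- assembleInputs(tr, te)
  expect_identical(inp$slots, c("mutation", "tissue", "pathway",
                                "expression"))
  expect_identical(colnames(inp$train), inp$slots)
  expect_identical(dim(inp$test), dim(inp$train))

  none <- list(mutation = rep(0.4, 3), pathway = rep(0.1, 3))
  expect_error(assembleInputs(none), "no informative",
               class = "twoStepValidationError")

  allGood <- lapply(stats::setNames(canonicalLayers(), canonicalLayers()),
                    function(s) c(0.1, 0.5, 0.9))
  allGood <- lapply(allGood, jitter)
  expect_length(assembleInputs(allGood)$slots, 6)
})

test_that("the registry holds 13 algorithms with declared capabilities", {
  reg <- algorithmRegistry()
  expect_equal(nrow(reg), 13)
  expect_false(reg$usesScore[reg$id == "nb"])
  expect_true(all(reg$usesScore[reg$id != "nb"]))
  expect_false(any(reg$hasImportance[reg$id %in% c("nb", "nnet")]))
})

test_that("every algorithm separates linearly separable inputs in training", {
  inp <- makeInputs(n = 40)
  for (alg in algorithmRegistry()$id) {
    model <- fitSecondStep(inp$x, inp$y, alg, seed = 7)
    pred <- predict(model, inp$x, type = "class")
    expect_gte(mean(pred == inp$y), 0.95)
  }
})

test_that("single-class training labels are rejected", {
  inp <- makeInputs(n = 20)
  expect_error(fitSecondStep(inp$x, rep(1, 20), "logit"),
               class = "twoStepValidationError")
  expect_error(fitSecondStep(inp$x, inp$y, "no-such-algorithm"),
               class = "twoStepValidationError")
})

test_that("importances single out the informative input", {
  inp <- makeInputs(n = 80, informative = "pathway", seed = 5)
  for (alg in c("svm_c1", "lm_ols", "lm_ridge", "logit", "logit_enet",
                "bag", "boost")) {
    model <- fitSecondStep(inp$x, inp$y, alg, seed = 11)
    imp <- extractImportances(model)
    expect_equal(max(imp), 1)
    expect_identical(names(imp)[which.max(imp)], "pathway")
  }
  # explicit not-available marker for naive Bayes and the neural network
  expect_null(extractImportances(fitSecondStep(inp$x, inp$y, "nb", 1)))
  expect_null(extractImportances(fitSecondStep(inp$x, inp$y, "nnet", 1)))
})

test_that("duplicated inputs share weight under L2 regularization", {
  withr::with_seed(19, {
    n <- 200
    y <- rep(c(0, 1), each = n / 2)
    sig <- y + rnorm(n, sd = 0.5)
    x <- cbind(mutation = sig, cnv = sig,
               pathway = rnorm(n))
    rownames(x) <- sprintf("C%03d", 1:n)
    model <- fitSecondStep(x, y, "lm_ridge", seed = 2)
    imp <- extractImportances(model)
    expect_equal(unname(imp["mutation"]), unname(imp["cnv"]),
                 tolerance = 0.1)
    expect_lt(imp["pathway"], 0.5)
  })
})

test_that("confusion metrics follow their definitions", {
  pred <- rep(c(1, 1, 0, 0), c(3, 1, 2, 4))
  truth <- rep(c(1, 0, 1, 0), c(3, 1, 2, 4))
  m <- computeMetrics(pred, truth)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.6)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["fdr"]), 0.25)

  perfect <- computeMetrics(truth, truth)
  expect_equal(unname(perfect["accuracy"]), 1)
  expect_equal(unname(perfect["fdr"]), 0)

  noPos <- computeMetrics(rep(0, 4), c(1, 0, 1, 0))
  expect_true(is.na(noPos["precision"]) && is.na(noPos["fdr"]))

  expect_error(computeMetrics(c(1, 0), c(1, 0, 1)),
               class = "twoStepValidationError")

  # fdr + precision = 1 whenever both are defined (random instances)
  withr::with_seed(23, {
    for (i in 1:100) {
      p <- rbinom(20, 1, 0.5)
      t <- rbinom(20, 1, 0.5)
      m <- computeMetrics(p, t)
      if (!is.na(m["precision"]))
        expect_equal(unname(m["precision"] + m["fdr"]), 1,
                     tolerance = 1e-12)
    }
  })
})

test_that("ROC-AUC equals the all-pairs oracle and is rank-invariant", {
  expect_equal(computeRocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(computeRocAuc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(computeRocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               pairwiseAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_true(is.na(computeRocAuc(1:4, rep(1, 4))))

  withr::with_seed(29, {
    for (i in 1:100) {
      n <- sample(6:30, 1)
      s <- round(rnorm(n), 1)        # provoke ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      auc <- computeRocAuc(s, y)
      expect_equal(auc, pairwiseAuc(s, y), tolerance = 1e-10)
      # strictly monotone transforms leave the AUC unchanged
      expect_equal(computeRocAuc(exp(2 * s), y), auc, tolerance = 1e-12)
    }
  })
})
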