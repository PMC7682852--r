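# ---- algorithm registry -----------------------------------------------
#
# Thirteen second-step fitting algorithms spanning a naive Bayes
# classifier, a shallow neural network, two linear-kernel SVMs, bagged
# and boosted tree ensembles, and linear / logistic regressions with
# several regularization schemes. The registry is data-driven so the
# roster can be replaced; each entry provides fit / score / weights
# hooks. Inputs arrive z-scored on the training fold.

.cvFoldid <- function(n, k = 5L) {
  # deterministic inner-CV fold ids (caller controls the RNG state)
  sample(rep_len(seq_len(k), n))
}

.glmnetFit <- function(x, y, alpha, family) {
  if (ncol(x) < 2L) {
    # glmnet needs two or more columns; with a single surviving input the
    # regularization path is moot and an unpenalized fit is used
    if (family == "gaussian") {
      cf <- .lsFit(x, y)$coefficients
    } else {
      cf <- suppressWarnings(stats::coef(stats::glm.fit(cbind(1, x), y,
                             family = stats::binomial())))
      names(cf) <- c("(Intercept)", colnames(x))
    }
    return(structure(list(coef = cf, family = family), class = "tsoPlainFit"))
  }
  foldid <- .cvFoldid(length(y))
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, family = family,
                          nfolds = 5L, foldid = foldid,
                          standardize = FALSE)
  structure(list(cv = cv, family = family), class = "tsoGlmnetFit")
}

.glmnetScore <- function(fit, x) {
  if (inherits(fit, "tsoPlainFit")) {
    eta <- drop(cbind(1, x) %*% fit$coef)
    return(if (fit$family == "binomial") stats::plogis(eta) else eta)
  }
  drop(stats::predict(fit$cv, newx = x, s = "lambda.min",
                      type = "response"))
}

.glmnetWeights <- function(fit) {
  if (inherits(fit, "tsoPlainFit")) return(abs(fit$coef[-1L]))
  cf <- as.matrix(stats::coef(fit$cv, s = "lambda.min"))
  abs(cf[-1L, 1L])
}

.svmScore <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  # orient the margin so that larger values favour the responder class
  if (grepl("^0/", colnames(dv)[1L])) dv <- -dv
  drop(dv)
}

.svmWeights <- function(fit) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  abs(stats::setNames(w, colnames(fit$SV)))
}

.makeRegistry <- function() {
  reg <- list(
    nb = list(
      label = "naive Bayes", usesScore = FALSE, hasImportance = FALSE,
      fit = function(x, y) e1071::naiveBayes(as.data.frame(x),
                                             factor(y, levels = c(0, 1))),
      score = function(fit, x)
        as.numeric(as.character(stats::predict(fit, as.data.frame(x)))),
      weights = function(fit) NULL),
    nnet = list(
      label = "neural network (10 hidden units)", usesScore = TRUE,
      hasImportance = FALSE,
      fit = function(x, y) nnet::nnet(x, y, size = 10L, decay = 0.1,
                                      maxit = 200L, trace = FALSE),
      score = function(fit, x) as.vector(stats::predict(fit, x)),
      weights = function(fit) NULL),
    svm_c1 = list(
      label = "linear SVM (C = 1)", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) e1071::svm(x, factor(y, levels = c(0, 1)),
                                      kernel = "linear", cost = 1,
                                      scale = FALSE),
      score = .svmScore, weights = .svmWeights),
    svm_c01 = list(
      label = "linear SVM (C = 0.1)", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) e1071::svm(x, factor(y, levels = c(0, 1)),
                                      kernel = "linear", cost = 0.1,
                                      scale = FALSE),
      score = .svmScore, weights = .svmWeights),
    bag = list(
      label = "bagged tree ensemble", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = 100L, mtry = ncol(x)),
      score = function(fit, x) stats::predict(fit, x, type = "prob")[, "1"],
      weights = function(fit)
        stats::setNames(fit$importance[, "MeanDecreaseGini"],
                        rownames(fit$importance))),
    boost = list(
      label = "boosted tree ensemble", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) {
        dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
        booster <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3L,
                        eta = 0.3, nthread = 1L),
          data = dm, nrounds = 30L, verbose = 0)
        list(booster = booster, features = colnames(x))
      },
      score = function(fit, x) stats::predict(fit$booster, x),
      weights = function(fit) {
        imp <- xgboost::xgb.importance(model = fit$booster)
        w <- stats::setNames(rep(0, length(fit$features)), fit$features)
        if (nrow(imp)) w[imp$Feature] <- imp$Gain
        w
      }),
    lm_ols = list(
      label = "linear regression", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) list(coef = .lsFit(x, y)$coefficients),
      score = function(fit, x) drop(cbind(1, x) %*% fit$coef),
      weights = function(fit) abs(fit$coef[-1L])),
    lm_ridge = list(
      label = "ridge linear regression", usesScore = TRUE,
      hasImportance = TRUE,
      fit = function(x, y) .glmnetFit(x, y, alpha = 0, family = "gaussian"),
      score = .glmnetScore, weights = .glmnetWeights),
    lm_lasso = list(
      label = "lasso linear regression", usesScore = TRUE,
      hasImportance = TRUE,
      fit = function(x, y) .glmnetFit(x, y, alpha = 1, family = "gaussian"),
      score = .glmnetScore, weights = .glmnetWeights),
    lm_enet = list(
      label = "elastic-net linear regression", usesScore = TRUE,
      hasImportance = TRUE,
      fit = function(x, y) .glmnetFit(x, y, alpha = 0.5,
                                      family = "gaussian"),
      score = .glmnetScore, weights = .glmnetWeights),
    logit = list(
      label = "logistic regression", usesScore = TRUE, hasImportance = TRUE,
      fit = function(x, y) {
        cf <- suppressWarnings(stats::coef(stats::glm.fit(
          cbind(1, x), y, family = stats::binomial())))
        cf[is.na(cf)] <- 0
        names(cf) <- c("(Intercept)", colnames(x))
        list(coef = cf)
      },
      score = function(fit, x) stats::plogis(drop(cbind(1, x) %*% fit$coef)),
      weights = function(fit) abs(fit$coef[-1L])),
    logit_lasso = list(
      label = "lasso logistic regression", usesScore = TRUE,
      hasImportance = TRUE,
      fit = function(x, y) .glmnetFit(x, y, alpha = 1, family = "binomial"),
      score = .glmnetScore, weights = .glmnetWeights),
    logit_enet = list(
      label = "elastic-net logistic regression", usesScore = TRUE,
      hasImportance = TRUE,
      fit = function(x, y) .glmnetFit(x, y, alpha = 0.5,
                                      family = "binomial"),
      score = .glmnetScore, weights = .glmnetWeights))
  reg
}

.registry <- .makeRegistry()

#' The second-step algorithm registry
#'
#' @return data.frame describing the 13 integration algorithms: id,
#'   label, whether a continuous score (and hence a ROC-AUC) is produced,
#'   and whether input weights/importances are available.
#' @export
algorithmRegistry <- function() {
  data.frame(id = names(.registry),
             label = vapply(.registry, `[[`, "", "label"),
             usesScore = vapply(.registry, `[[`, NA, "usesScore"),
             hasImportance = vapply(.registry, `[[`, NA, "hasImportance"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- input assembly ----------------------------------------------------

#' Assemble second-step inputs from first-step outputs
#'
#' Drops first-step output vectors that are constant on the training fold
#' (models that found no statistically significant relation) and binds
#' the remainder, in canonical layer order, into the input matrices of
#' the integration step.
#'
#' @param trainPreds named list of training prediction vectors (pre-
#'   binarization, `[0, 1]` scale); `NULL` entries are ignored.
#' @param testPreds matching list of test prediction vectors.
#' @return List with `train` (matrix), `test` (matrix or `NULL`) and
#'   `slots` (surviving layer names).
#' @export
assembleInputs <- function(trainPreds, testPreds = NULL) {
  ord <- intersect(canonicalLayers(), names(trainPreds))
  keep <- character()
  for (nm in ord) {
    v <- trainPreds[[nm]]
    if (is.null(v)) next
    if (length(unique(v)) > 1L) keep <- c(keep, nm)
  }
  if (!length(keep))
    .validationError("no informative first-step models")
  train <- do.call(cbind, trainPreds[keep])
  colnames(train) <- keep
  test <- NULL
  if (!is.null(testPreds)) {
    test <- do.call(cbind, testPreds[keep])
    colnames(test) <- keep
  }
  list(train = train, test = test, slots = keep)
}

# ---- fitting -----------------------------------------------------------

#' Fit one integrated second-step model
#'
#' Standardizes the input matrix (z-score on training statistics, so
#' extracted weights are comparable across slots), fits the requested
#' registry algorithm under a controlled seed, and for score-producing
#' algorithms derives the accuracy-optimal binarization cutoff via
#' [normalizeAndCut()]. A fit that fails to converge is flagged and
#' replaced by a majority-class fallback.
#'
#' @param x training input matrix from [assembleInputs()].
#' @param y binarized training labels (0/1), both classes present.
#' @param algorithmId registry id, see [algorithmRegistry()].
#' @param seed integer seed for stochastic fitters (neural network
#'   initialization, bagging, boosting, inner CV folds).
#' @return An [IntegrationModel-class].
#' @export
fitSecondStep <- function(x, y, algorithmId, seed = 1L) {
  if (!algorithmId %in% names(.registry))
    .validationError(sprintf("unknown algorithm '%s'", algorithmId))
  if (length(unique(y)) < 2L)
    .validationError("training labels contain a single class")
  entry <- .registry[[algorithmId]]
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  fallback <- as.numeric(mean(y) >= 0.5)
  fit <- tryCatch(.withSeed(seed, entry$fit(xs, y)), error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("IntegrationModel", algorithmId = algorithmId,
               inputSlots = colnames(x), fit = NULL, center = center,
               scale = scl, bounds = c(NA_real_, NA_real_),
               cutoff = NA_real_, usesScore = entry$usesScore,
               constant = TRUE, fallbackClass = fallback,
               converged = FALSE))
  }
  bounds <- c(NA_real_, NA_real_)
  cutoff <- NA_real_
  constant <- FALSE
  if (entry$usesScore) {
    trainScore <- entry$score(fit, xs)
    nc <- normalizeAndCut(trainScore, NULL, y)
    constant <- nc$constant
    if (!constant) {
      bounds <- nc$bounds
      cutoff <- nc$cutoff
    }
  }
  new("IntegrationModel", algorithmId = algorithmId,
      inputSlots = colnames(x), fit = fit, center = center, scale = scl,
      bounds = bounds, cutoff = cutoff, usesScore = entry$usesScore,
      constant = constant, fallbackClass = fallback, converged = TRUE)
}

#' Predict from an integrated second-step model
#'
#' @param object an [IntegrationModel-class].
#' @param newdata input matrix with the model's `inputSlots` columns.
#' @param type `"class"` (default), `"normalized"` (score scaled with the
#'   training bounds, clipped to `[0, 1]`) or `"score"` (raw). The naive
#'   Bayes classifier only produces hard labels, returned for every type.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
setMethod("predict", "IntegrationModel",
          function(object, newdata, type = c("class", "normalized",
                                             "score"), ...) {
  type <- match.arg(type)
  newdata <- newdata[, object@inputSlots, drop = FALSE]
  nms <- rownames(newdata)
  if (!object@converged || (object@constant && object@usesScore)) {
    out <- rep(if (type == "class") object@fallbackClass
               else object@fallbackClass, nrow(newdata))
    return(stats::setNames(out, nms))
  }
  entry <- .registry[[object@algorithmId]]
  xs <- scale(newdata, center = object@center, scale = object@scale)
  score <- entry$score(object@fit, xs)
  if (!object@usesScore)          # hard-label classifier
    return(stats::setNames(score, nms))
  if (type == "score") return(stats::setNames(score, nms))
  norm <- pmin(pmax((score - object@bounds[1L]) / diff(object@bounds), 0), 1)
  if (type == "normalized") return(stats::setNames(norm, nms))
  stats::setNames(as.numeric(norm >= object@cutoff), nms)
})

setMethod("show", "IntegrationModel", function(object) {
  cat(sprintf("IntegrationModel '%s' on [%s]%s\n", object@algorithmId,
              paste(object@inputSlots, collapse = ", "),
              if (!object@converged) " (fallback: did not converge)"
              else if (object@constant) " (constant output)" else ""))
})

#' Extract input weights / importances
#'
#' Absolute coefficients on the standardized inputs (linear and logistic
#' regressions, linear SVMs) or impurity/gain importances (tree
#' ensembles), rescaled so the maximum equals 1 within the model. The
#' neural network and the naive Bayes classifier do not support
#' importances and yield `NULL` - an explicit "not available" marker,
#' never zeros.
#'
#' @param model an [IntegrationModel-class].
#' @return Named numeric vector (max 1), or `NULL` when unavailable.
#' @export
extractImportances <- function(model) {
  entry <- .registry[[model@algorithmId]]
  if (!entry$hasImportance || !model@converged) return(NULL)
  w <- entry$weights(model@fit)
  w <- abs(as.numeric(w)[match(model@inputSlots, names(w))])
  names(w) <- model@inputSlots
  w[is.na(w)] <- 0
  if (max(w) > 0) w <- w / max(w)
  w
}

# ---- evaluation metrics ------------------------------------------------

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall, F1 and false discovery rate of binary
#' predictions. Metrics with a zero denominator (e.g. precision without
#' predicted positives) are reported as `NA` and excluded from fold
#' averages downstream. `fdr = 1 - precision` whenever both are defined.
#'
#' @param pred,truth equal-length binary (0/1) vectors.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `fdr`.
#' @export
computeMetrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    .validationError("prediction and truth lengths differ")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = (tp + tn) / length(pred), precision = precision,
    recall = recall, f1 = f1,
    fdr = if (is.na(precision)) NA_real_ else 1 - precision)
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney form with midrank tie handling: the probability that a
#' randomly drawn responder scores above a randomly drawn non-responder,
#' counting ties as one half.
#'
#' @param scores continuous prediction scores.
#' @param truth binary (0/1) labels.
#' @return AUC in `[0, 1]`, or `NA` when one class is absent.
#' @export
computeRocAuc <- function(scores, truth) {
  if (length(scores) != length(truth))
    .validationError("score and truth lengths differ")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
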