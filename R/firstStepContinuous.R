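# Accuracy-optimal threshold on values in [0, 1]. Candidates are the
# midpoints between consecutive sorted unique values, plus 0 (predict
# everything responder) and a sentinel 2 (predict nothing responder), so
# the chosen cutoff is never worse than either constant classifier.
# Ties pick the smallest candidate so responders are not under-called.
.chooseCutoff <- function(values, labels) {
  su <- sort(unique(values))
  mids <- if (length(su) > 1L) (su[-1L] + su[-length(su)]) / 2 else numeric()
  candidates <- c(0, mids, 2)
  acc <- vapply(candidates,
                function(ct) mean(as.numeric(values >= ct) == labels),
                numeric(1L))
  best <- which.max(acc)      # first maximum = smallest candidate
  list(cutoff = candidates[best], accuracy = acc[best])
}

#' Normalize model outputs and derive the binarization cutoff
#'
#' Min-max normalizes raw prediction vectors to `[0, 1]` using the
#' training bounds only (test values are clipped), then picks the cutoff
#' from the midpoints between consecutive sorted unique normalized
#' training predictions - plus the two constant classifiers - such that
#' training accuracy is maximal. Predictions at or above the cutoff are
#' class 1.
#'
#' @param rawTrain,rawTest raw (finite) prediction vectors; `rawTest` may
#'   be `NULL`.
#' @param binLabels binarized training labels (0/1).
#' @return List with `normTrain`, `normTest`, `bounds`, `cutoff`,
#'   `trainAccuracy`, `binTrain`, `binTest` and `constant` (`TRUE` when
#'   the raw training predictions are constant; such a model is flagged
#'   and excluded from the second step).
#' @export
normalizeAndCut <- function(rawTrain, rawTest = NULL, binLabels) {
  if (any(!is.finite(rawTrain)))
    .validationError("raw training predictions must be finite")
  bounds <- range(rawTrain)
  if (diff(bounds) == 0) {
    return(list(normTrain = rep(0, length(rawTrain)), normTest = NULL,
                bounds = bounds, cutoff = NA_real_,
                trainAccuracy = NA_real_, binTrain = NULL, binTest = NULL,
                constant = TRUE))
  }
  normTrain <- (rawTrain - bounds[1L]) / diff(bounds)
  cut <- .chooseCutoff(normTrain, binLabels)
  normTest <- NULL
  binTest <- NULL
  if (!is.null(rawTest)) {
    normTest <- pmin(pmax((rawTest - bounds[1L]) / diff(bounds), 0), 1)
    binTest <- as.numeric(normTest >= cut$cutoff)
    names(normTest) <- names(rawTest)
    names(binTest) <- names(rawTest)
  }
  list(normTrain = stats::setNames(normTrain, names(rawTrain)),
       normTest = normTest, bounds = bounds, cutoff = cut$cutoff,
       trainAccuracy = cut$accuracy,
       binTrain = stats::setNames(as.numeric(normTrain >= cut$cutoff),
                                  names(rawTrain)),
       binTest = binTest, constant = FALSE)
}

# least-squares fit with intercept returning coefficients and two-sided
# p-values; aliased columns get zero coefficients and NA p-values
.lsFit <- function(x, y) {
  df <- data.frame(y = y, x, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  aliased <- is.na(cf)
  if (any(aliased[-1L]))
    message(sprintf("collinear predictors dropped from least squares: %s",
                    paste(names(cf)[-1L][aliased[-1L]], collapse = ", ")))
  sm <- summary(fit)$coefficients
  pv <- rep(NA_real_, length(cf))
  names(pv) <- names(cf)
  pv[rownames(sm)] <- sm[, 4L]
  cf[aliased] <- 0
  list(coefficients = cf, pvalues = pv)
}

#' Fit the gene-expression first-step model
#'
#' Principal component analysis (centered, unscaled - RMA expression is
#' already on a common log scale) is computed on the training cell lines
#' only; the scores of the first `nComponents` components (all available
#' components when the rank is lower) are regressed on the binarized
#' response by least squares. The raw fitted values are normalized and
#' cut via [normalizeAndCut()].
#'
#' @param exprTrain continuous training expression matrix (cells x
#'   genes), at least 8 rows.
#' @param binLabels binarized training labels (0/1).
#' @param nComponents number of principal components, default 7.
#' @return A [ContinuousFirstStepModel-class].
#' @export
fitExpressionModel <- function(exprTrain, binLabels, nComponents = 7L) {
  if (nrow(exprTrain) < 8L)
    .validationError("need at least 8 training cell lines")
  pr <- stats::prcomp(exprTrain, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1L] * 1e-8)
  ncomp <- min(as.integer(nComponents), rank)
  if (ncomp == 0L) {
    return(new("ContinuousFirstStepModel", dataType = "expression",
               center = colMeans(exprTrain), loadings = matrix(0, 0L, 0L),
               coefficients = c(`(Intercept)` = mean(binLabels)),
               coefPvalues = NA_real_, bounds = c(0, 0), cutoff = NA_real_,
               nComponents = 0L, constant = TRUE))
  }
  scores <- pr$x[, seq_len(ncomp), drop = FALSE]
  ls <- .lsFit(scores, binLabels)
  raw <- drop(cbind(1, scores) %*% ls$coefficients)
  nc <- normalizeAndCut(raw, NULL, binLabels)
  new("ContinuousFirstStepModel", dataType = "expression",
      center = pr$center,
      loadings = pr$rotation[, seq_len(ncomp), drop = FALSE],
      coefficients = ls$coefficients, coefPvalues = ls$pvalues,
      bounds = nc$bounds, cutoff = if (nc$constant) NA_real_ else nc$cutoff,
      nComponents = ncomp, constant = nc$constant)
}

#' Fit the pathway-activation first-step model
#'
#' Least-squares regression of the binarized response on the pathway
#' activation scores (no dimension reduction; the default input carries
#' the 11 PROGENy pathways). Per-pathway coefficient p-values are
#' retained for reporting.
#'
#' @param pathTrain continuous training score matrix (cells x pathways).
#' @param binLabels binarized training labels (0/1).
#' @return A [ContinuousFirstStepModel-class].
#' @export
fitPathwayModel <- function(pathTrain, binLabels) {
  if (nrow(pathTrain) < 8L)
    .validationError("need at least 8 training cell lines")
  ls <- .lsFit(pathTrain, binLabels)
  raw <- drop(cbind(1, pathTrain) %*% ls$coefficients)
  nc <- normalizeAndCut(raw, NULL, binLabels)
  new("ContinuousFirstStepModel", dataType = "pathway",
      center = stats::setNames(numeric(ncol(pathTrain)), colnames(pathTrain)),
      loadings = matrix(0, 0L, 0L),
      coefficients = ls$coefficients, coefPvalues = ls$pvalues,
      bounds = nc$bounds, cutoff = if (nc$constant) NA_real_ else nc$cutoff,
      nComponents = as.integer(ncol(pathTrain)), constant = nc$constant)
}

#' Predict from a continuous first-step model
#'
#' Projects new data with the training centering/loadings (expression) or
#' uses the raw scores (pathway), applies the regression coefficients and
#' returns raw, normalized (clipped to `[0, 1]` with training bounds) or
#' binarized predictions.
#'
#' @param object a [ContinuousFirstStepModel-class].
#' @param newdata value matrix of the model's layer.
#' @param type `"normalized"` (default), `"raw"` or `"class"`.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
setMethod("predict", "ContinuousFirstStepModel",
          function(object, newdata, type = c("normalized", "raw", "class"),
                   ...) {
  type <- match.arg(type)
  if (object@constant) {
    out <- rep(if (type == "raw") object@coefficients[[1L]] else 0,
               nrow(newdata))
    names(out) <- rownames(newdata)
    return(out)
  }
  if (object@dataType == "expression") {
    centered <- sweep(newdata[, names(object@center), drop = FALSE], 2L,
                      object@center)
    design <- centered %*% object@loadings
  } else {
    design <- newdata[, names(object@center), drop = FALSE]
  }
  raw <- drop(cbind(1, design) %*% object@coefficients)
  names(raw) <- rownames(newdata)
  if (type == "raw") return(raw)
  norm <- pmin(pmax((raw - object@bounds[1L]) / diff(object@bounds), 0), 1)
  if (type == "normalized") return(norm)
  stats::setNames(as.numeric(norm >= object@cutoff), names(raw))
})

setMethod("show", "ContinuousFirstStepModel", function(object) {
  cat(sprintf("ContinuousFirstStepModel (%s): %s\n", object@dataType,
              if (object@constant) "constant (flagged)"
              else sprintf("%d predictors, cutoff %.3f",
                           object@nComponents, object@cutoff)))
})
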