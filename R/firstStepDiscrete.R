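#' Count-screen discrete features
#'
#' A genomic feature (mutation, CNV, hypermethylation) is a candidate for
#' association testing only when at least `minCount` training cell lines
#' carry each of two distinct states; for ternary CNV columns the split is
#' aberrant (any non-zero state) versus neutral. A tissue type is a
#' candidate when at least `minCount` training cell lines belong to it.
#' Features failing the screen are temporarily discarded for the fold.
#'
#' @param values training-cell value matrix of one layer.
#' @param dtypeClass `"binary"`, `"ternary"` or `"onehot"`.
#' @param minCount minimum state count: the pipeline default is 15 for
#'   genomic layers and 10 for tissue.
#' @return Character vector of candidate feature names (possibly empty).
#' @export
screenFeatures <- function(values, dtypeClass, minCount) {
  present <- colSums(values != 0)
  if (dtypeClass == "onehot") {
    keep <- present >= minCount
  } else {
    keep <- present >= minCount & (nrow(values) - present) >= minCount
  }
  colnames(values)[keep]
}

# Vectorized two-sample t-test of the continuous response between cells
# where a feature is present (non-zero) and absent. Pooled-variance
# Student's t by default, Welch optionally. Degenerate zero-variance
# splits follow the documented convention: equal means give p = 1,
# unequal means p = 0.
.rowTTest <- function(presence, y, varEqual = TRUE) {
  presence <- presence * 1
  n <- length(y)
  n1 <- colSums(presence)
  n0 <- n - n1
  s1 <- as.vector(crossprod(presence, y))
  ss1 <- as.vector(crossprod(presence, y^2))
  m1 <- s1 / n1
  m0 <- (sum(y) - s1) / n0
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  v0 <- ((sum(y^2) - ss1) - n0 * m0^2) / (n0 - 1)
  # guard against catastrophic cancellation on constant groups
  tol <- 1e-12 * (stats::var(y) + .Machine$double.eps)
  v1[v1 < tol] <- 0
  v0[v0 < tol] <- 0
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n - 2, length(n1))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- !is.finite(se) | se == 0
  if (any(zero)) {
    eq <- abs(m1 - m0) <= sqrt(.Machine$double.eps) * (abs(m0) + abs(m1) + 1)
    p[zero] <- ifelse(eq[zero], 1, 0)
    t[zero] <- ifelse(eq[zero], 0, sign(m1 - m0)[zero] * Inf)
  }
  data.frame(feature = colnames(presence), n1 = n1, n0 = n0,
             mean1 = m1, mean0 = m0, t = t, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided t-test of feature association with responsiveness
#'
#' Tests whether the continuous (pre-binarization) dose-response AUC
#' differs between cell lines where a feature is present and where it is
#' absent. Pooled-variance Student's t is the default; Welch's unequal
#' variance test is available via `varEqual = FALSE`. With zero variance
#' in both groups the p-value is 1 for equal means and 0 otherwise.
#'
#' @param presentAuc,absentAuc continuous response values of the two
#'   groups, each with at least 2 values.
#' @param varEqual pool the variances (default `TRUE`).
#' @return Two-sided p-value.
#' @export
testFeatureAssociation <- function(presentAuc, absentAuc, varEqual = TRUE) {
  if (length(presentAuc) < 2L || length(absentAuc) < 2L)
    .validationError("both groups need at least 2 values")
  y <- c(presentAuc, absentAuc)
  presence <- matrix(rep(c(1, 0), c(length(presentAuc), length(absentAuc))),
                     ncol = 1L, dimnames = list(NULL, "f"))
  .rowTTest(presence, y, varEqual = varEqual)$p
}

#' Bonferroni feature selection
#'
#' Keeps the features with `p <= alpha / m`, ordered by ascending p-value
#' (ties keep the incoming column order). `m` is the number of features
#' that passed the count screen in the fold, i.e. the number of tests
#' actually performed.
#'
#' @param pvalues named numeric vector of per-feature p-values.
#' @param alpha family significance level, default 0.05.
#' @param m Bonferroni divisor, defaults to `length(pvalues)`.
#' @return Character vector of significant feature names.
#' @export
bonferroniSelect <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  if (m < 1L) .validationError("m must be at least 1")
  sel <- which(pvalues <= alpha / m)
  names(pvalues)[sel][order(pvalues[sel])]
}

#' Remove pattern-redundant features
#'
#' Two features are redundant when they are present and absent in exactly
#' the same training cell lines. Among features sharing one presence
#' pattern only the first (smallest p-value, then earlier column) is
#' kept; the map of discarded-to-kept links is returned so the full
#' feature set can still be reported.
#'
#' @param presence logical/0-1 matrix (training cells x features) with
#'   columns ordered by ascending p-value.
#' @return List with `kept` (character) and `redundancyMap` (named
#'   character, discarded -> kept).
#' @export
removeRedundant <- function(presence) {
  if (ncol(presence) == 0L)
    return(list(kept = character(), redundancyMap = character()))
  keys <- apply(presence != 0, 2L,
                function(col) paste0(as.integer(col), collapse = ""))
  dup <- duplicated(keys)
  kept <- colnames(presence)[!dup]
  map <- character()
  if (any(dup)) {
    firstOf <- stats::setNames(colnames(presence)[!dup], keys[!dup])
    map <- stats::setNames(unname(firstOf[keys[dup]]),
                           colnames(presence)[dup])
  }
  list(kept = kept, redundancyMap = map)
}

#' Build a discrete cluster model
#'
#' Sorts the training cell lines into up to `2^n` clusters defined by the
#' presence/absence pattern over the `n` significant non-redundant
#' features (capped at `featureCap`, keeping the smallest p-values).
#' Empty clusters are absent; each remaining cluster predicts its mean
#' binarized responsiveness. With `n = 0` the model is the single trivial
#' cluster whose constant prediction is the training responder fraction.
#'
#' @param values training value matrix of the layer (raw states; presence
#'   is any non-zero value).
#' @param features significant non-redundant feature names, ordered by
#'   ascending p-value.
#' @param binLabels binarized training labels (0/1).
#' @param dataType layer name.
#' @param featureCap maximum number of clustering features (default 10,
#'   i.e. at most 1024 clusters).
#' @param relevant data.frame describing the full significant set (stored
#'   for reporting).
#' @param redundancyMap named character vector from [removeRedundant()].
#' @return A [ClusterModel-class].
#' @export
buildClusterModel <- function(values, features, binLabels,
                              dataType = "mutation", featureCap = 10L,
                              relevant = NULL, redundancyMap = character()) {
  if (length(features) > featureCap) features <- features[seq_len(featureCap)]
  fallback <- mean(binLabels)
  if (is.null(relevant))
    relevant <- data.frame(feature = character(), p = numeric(),
                           nPresent = integer(), direction = character(),
                           redundant = logical(), stringsAsFactors = FALSE)
  if (!length(features)) {
    return(new("ClusterModel", dataType = dataType, relevant = relevant,
               nonredundant = character(), redundancyMap = redundancyMap,
               clusters = data.frame(pattern = "", n = length(binLabels),
                                     prediction = fallback,
                                     stringsAsFactors = FALSE),
               states = matrix(0, 1L, 0L), fallback = fallback,
               cutoff = NA_real_, constant = TRUE))
  }
  sub <- values[, features, drop = FALSE]
  presence <- sub != 0
  keys <- .patternKeys(presence)
  uk <- sort(unique(keys))
  counts <- as.integer(table(keys)[uk])
  preds <- vapply(uk, function(k) mean(binLabels[keys == k]), numeric(1L))
  # representative state per cluster and feature: the pattern bit itself,
  # refined for ternary data to the modal non-zero state among members
  states <- matrix(0, length(uk), length(features),
                   dimnames = list(uk, features))
  for (i in seq_along(uk)) {
    members <- keys == uk[i]
    for (j in seq_along(features)) {
      if (substr(uk[i], j, j) == "1") {
        vals <- sub[members, j]
        states[i, j] <- .modalValue(vals[vals != 0])
      }
    }
  }
  new("ClusterModel", dataType = dataType, relevant = relevant,
      nonredundant = features, redundancyMap = redundancyMap,
      clusters = data.frame(pattern = uk, n = counts, prediction = preds,
                            stringsAsFactors = FALSE, row.names = NULL),
      states = states, fallback = fallback, cutoff = NA_real_,
      constant = length(unique(preds)) <= 1L)
}

#' Build the tissue first-step model
#'
#' With `n` significant tissue types, cell lines are sorted into `n + 1`
#' clusters: the first pools all remaining (non-significant) tissues, the
#' following clusters correspond to the significant tissues in the order
#' of the significance list. No redundancy pruning applies to one-hot
#' tissue columns.
#'
#' @param values one-hot training tissue matrix.
#' @param sigTissues significant tissue names ordered by ascending
#'   p-value.
#' @param binLabels binarized training labels (0/1).
#' @param relevant reporting data.frame, as in [buildClusterModel()].
#' @return A [ClusterModel-class] with `dataType = "tissue"`; the cluster
#'   `pattern` is the tissue name, `"<other>"` for the pooled cluster.
#' @export
buildTissueModel <- function(values, sigTissues, binLabels, relevant = NULL) {
  fallback <- mean(binLabels)
  if (is.null(relevant))
    relevant <- data.frame(feature = character(), p = numeric(),
                           nPresent = integer(), direction = character(),
                           redundant = logical(), stringsAsFactors = FALSE)
  if (!length(sigTissues)) {
    return(new("ClusterModel", dataType = "tissue", relevant = relevant,
               nonredundant = character(), redundancyMap = character(),
               clusters = data.frame(pattern = "", n = length(binLabels),
                                     prediction = fallback,
                                     stringsAsFactors = FALSE),
               states = matrix(0, 1L, 0L), fallback = fallback,
               cutoff = NA_real_, constant = TRUE))
  }
  keys <- .tissueKeys(values, sigTissues)
  order <- c("<other>", sigTissues)
  present <- order[order %in% keys]       # empty clusters are discarded
  counts <- vapply(present, function(k) sum(keys == k), integer(1L))
  preds <- vapply(present, function(k) mean(binLabels[keys == k]),
                  numeric(1L))
  new("ClusterModel", dataType = "tissue", relevant = relevant,
      nonredundant = sigTissues, redundancyMap = character(),
      clusters = data.frame(pattern = present, n = unname(counts),
                            prediction = unname(preds),
                            stringsAsFactors = FALSE, row.names = NULL),
      states = matrix(0, length(present), 0L), fallback = fallback,
      cutoff = NA_real_, constant = length(unique(preds)) <= 1L)
}

.tissueKeys <- function(values, sigTissues) {
  keys <- rep("<other>", nrow(values))
  for (ts in sigTissues) {
    if (ts %in% colnames(values)) keys[values[, ts] != 0] <- ts
  }
  keys
}

#' Predict from a discrete cluster model
#'
#' Each cell line receives the mean binarized responsiveness of the
#' training cluster matching its presence/absence profile over the
#' model's non-redundant features; profiles that correspond to a cluster
#' empty in training fall back to the overall training responder
#' fraction.
#'
#' @param object a [ClusterModel-class].
#' @param newdata raw value matrix of the model's layer (all features;
#'   the relevant columns are picked by name).
#' @param ... unused.
#' @return Numeric predictions in `[0, 1]`, named by cell line.
#' @export
setMethod("predict", "ClusterModel", function(object, newdata, ...) {
  if (object@constant || !length(object@nonredundant)) {
    out <- rep(object@fallback, nrow(newdata))
    names(out) <- rownames(newdata)
    return(out)
  }
  if (object@dataType == "tissue") {
    keys <- .tissueKeys(newdata, object@nonredundant)
  } else {
    missing <- setdiff(object@nonredundant, colnames(newdata))
    if (length(missing))
      .validationError(sprintf("feature '%s' absent from prediction data",
                               missing[1L]))
    keys <- .patternKeys(newdata[, object@nonredundant, drop = FALSE] != 0)
  }
  lut <- stats::setNames(object@clusters$prediction, object@clusters$pattern)
  out <- unname(lut[keys])
  out[is.na(out)] <- object@fallback
  names(out) <- rownames(newdata)
  out
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel (%s): %s\n", object@dataType,
              if (object@constant) "trivial single cluster"
              else sprintf("%d features, %d clusters",
                           length(object@nonredundant),
                           nrow(object@clusters))))
})

# Full first-step fit on one discrete layer for one training fold:
# screen -> t-test -> Bonferroni -> (redundancy, cap) -> cluster model.
# The association test runs on the continuous pre-binarization response,
# cluster means on the binarized labels.
.fitFirstStepDiscrete <- function(values, dataType, auc, binLabels,
                                  alpha = 0.05, minCount = 15L,
                                  featureCap = 10L, varEqual = TRUE) {
  dtype <- switch(dataType, cnv = "ternary", tissue = "onehot", "binary")
  candidates <- screenFeatures(values, dtype, minCount)
  m <- length(candidates)
  emptyRel <- data.frame(feature = character(), p = numeric(),
                         nPresent = integer(), direction = character(),
                         redundant = logical(), stringsAsFactors = FALSE)
  if (m == 0L) {
    model <- if (dataType == "tissue")
      buildTissueModel(values, character(), binLabels, emptyRel)
    else
      buildClusterModel(values, character(), binLabels, dataType,
                        featureCap, emptyRel)
    return(list(model = model, m = 0L, tested = emptyRel))
  }
  tt <- .rowTTest(values[, candidates, drop = FALSE] != 0, auc,
                  varEqual = varEqual)
  pv <- stats::setNames(tt$p, tt$feature)
  sig <- bonferroniSelect(pv, alpha = alpha, m = m)
  # direction: responder fraction with the feature present minus absent;
  # a positive shift means the feature marks sensitivity
  dirOf <- function(f) {
    pres <- values[, f] != 0
    d <- mean(binLabels[pres]) - mean(binLabels[!pres])
    if (isTRUE(d < 0)) "resistance" else "sensitivity"
  }
  if (length(sig)) {
    presence <- values[, sig, drop = FALSE] != 0
    if (dataType == "tissue") {
      kept <- sig
      map <- character()
    } else {
      rr <- removeRedundant(presence)
      kept <- rr$kept
      map <- rr$redundancyMap
    }
    relevant <- data.frame(
      feature = sig,
      p = unname(pv[sig]),
      nPresent = colSums(presence),
      direction = vapply(sig, dirOf, character(1L)),
      redundant = sig %in% names(map),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    kept <- character()
    map <- character()
    relevant <- emptyRel
  }
  model <- if (dataType == "tissue")
    buildTissueModel(values, kept, binLabels, relevant)
  else
    buildClusterModel(values, kept, binLabels, dataType, featureCap,
                      relevant, map)
  list(model = model, m = m, tested = tt)
}
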