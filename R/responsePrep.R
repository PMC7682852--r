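#' Quartile thresholds of a training response vector
#'
#' Lower and upper quantiles (defaults 0.25/0.75) of the continuous
#' dose-response AUC values, computed with linear interpolation between
#' order statistics (R quantile type 7) so that binarized cell-line counts
#' are reproducible.
#'
#' @param auc numeric vector of training AUC values; at least 8 finite
#'   values are required.
#' @param quantiles length-2 numeric, lower and upper probability.
#' @return List with `q1`, `q3` and `degenerate` (`TRUE` when `q1 == q3`,
#'   e.g. for a constant vector; all cell lines are then labelled and none
#'   excluded).
#' @examples
#' computeQuartileThresholds(1:8) # q1 = 2.75, q3 = 6.25
#' @export
computeQuartileThresholds <- function(auc, quantiles = c(0.25, 0.75)) {
  auc <- auc[is.finite(auc)]
  if (length(auc) < 8L)
    .validationError("need at least 8 finite response values for thresholds")
  if (length(quantiles) != 2L || quantiles[1L] > quantiles[2L])
    .validationError("quantiles must be an increasing probability pair")
  q <- unname(stats::quantile(auc, quantiles, type = 7))
  list(q1 = q[1L], q3 = q[2L], degenerate = q[1L] == q[2L])
}

#' Binarize a response vector at quartile thresholds
#'
#' Cell lines with AUC at or below `q1` are responders (1), those at or
#' above `q3` are non-responders (0); lower AUC means higher sensitivity.
#' Under the default `quartile_exclude_middle` policy, cell lines strictly
#' between the thresholds are excluded (`NA`) and never enter training or
#' scoring. Under `quartile_full` the inter-quartile band is dichotomized
#' at the threshold midpoint instead, so every cell line is labelled.
#'
#' @param auc numeric vector (optionally named).
#' @param q1,q3 thresholds from [computeQuartileThresholds()].
#' @param policy `"quartile_exclude_middle"` (default) or
#'   `"quartile_full"`.
#' @return Numeric vector of labels in `{1, 0, NA}`, same names as `auc`.
#' @export
binarizeResponse <- function(auc, q1, q3,
                             policy = c("quartile_exclude_middle",
                                        "quartile_full")) {
  policy <- match.arg(policy)
  if (q1 > q3) .validationError("q1 must not exceed q3")
  labels <- rep(NA_real_, length(auc))
  labels[auc <= q1] <- 1
  labels[is.na(labels) & auc >= q3] <- 0
  if (policy == "quartile_full") {
    mid <- (q1 + q3) / 2
    middle <- is.na(labels)
    labels[middle] <- as.numeric(auc[middle] <= mid)
  }
  names(labels) <- names(auc)
  labels
}

#' Build the stratified cross-validation partition
#'
#' Assigns every labelled (non-excluded) cell line to exactly one test
#' fold, preserving the responder fraction within one cell line per fold.
#' Deterministic given the seed.
#'
#' @param labels named numeric vector in `{1, 0, NA}` as returned by
#'   [binarizeResponse()]; `NA` entries receive an `NA` fold.
#' @param nFolds number of folds, default 10.
#' @param seed integer seed.
#' @return A [FoldPartition-class].
#' @export
makeCVPartition <- function(labels, nFolds = 10L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  if (is.null(names(labels)))
    .validationError("labels must be named by cell-line identifiers")
  lab <- labels[!is.na(labels)]
  nPos <- sum(lab == 1)
  nNeg <- sum(lab == 0)
  if (nPos < nFolds || nNeg < nFolds)
    .validationError(sprintf(
      "need at least %d labelled cell lines per class (have %d responders, %d non-responders)",
      nFolds, nPos, nNeg))
  assignments <- rep(NA_integer_, length(labels))
  names(assignments) <- names(labels)
  .withSeed(seed, {
    pos <- sample(names(lab)[lab == 1])
    neg <- sample(names(lab)[lab == 0])
    # responder overflow goes to the first folds, non-responder overflow to
    # the last, keeping total fold sizes within one cell line of each other
    assignments[pos] <- rep_len(seq_len(nFolds), length(pos))
    assignments[neg] <- rep_len(rev(seq_len(nFolds)), length(neg))
  })
  new("FoldPartition", nFolds = nFolds, assignments = assignments,
      seed = as.integer(seed))
}

setMethod("show", "FoldPartition", function(object) {
  a <- object@assignments
  cat(sprintf("FoldPartition: %d folds over %d labelled cell lines (%d excluded), seed %d\n",
              object@nFolds, sum(!is.na(a)), sum(is.na(a)), object@seed))
})

#' @describeIn makeCVPartition test-fold identifiers of one fold.
#' @param partition a [FoldPartition-class].
#' @param fold fold index.
#' @export
testFoldIds <- function(partition, fold) {
  a <- partition@assignments
  names(a)[!is.na(a) & a == fold]
}
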