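#' Enumerate ablation input subsets
#'
#' All subsets of 1 up to `min(maxRemove, k - 1)` input slots to remove,
#' where `k` is the number of surviving first-step inputs; removing every
#' input is never enumerated, so at least one input always remains. The
#' order is deterministic: by subset size, then lexicographically in
#' canonical slot order. With six surviving inputs this yields the full
#' set of 41 subsets (6 + 15 + 20), with five inputs 25 (5 + 10 + 10).
#'
#' @param slots character vector of surviving input slot names in
#'   canonical order.
#' @param maxRemove maximum subset size, default 3.
#' @return List of character vectors (possibly empty when `k = 1`).
#' @examples
#' length(enumerateAblationSubsets(canonicalLayers())) # 41
#' @export
enumerateAblationSubsets <- function(slots, maxRemove = 3L) {
  k <- length(slots)
  if (k <= 1L) return(list())
  out <- list()
  for (s in seq_len(min(maxRemove, k - 1L)))
    out <- c(out, utils::combn(slots, s, simplify = FALSE))
  out
}

.subsetKey <- function(subset) paste(subset, collapse = "+")

#' Relative performance of an ablation model
#'
#' Mean ablation-model metric divided by the mean metric of the complete
#' model using all available inputs. Values near 1 mean no change, above
#' 1 improved predictivity (reported, not clipped), below 1 a loss.
#'
#' @param ablationMean mean test metric of the reduced model across its
#'   computed folds.
#' @param fullMean mean test metric of the full model across all folds;
#'   must be positive for the ratio to be defined.
#' @return Ratio, or `NA` when `fullMean` is zero/undefined.
#' @export
relativePerformance <- function(ablationMean, fullMean) {
  if (!is.finite(fullMean) || fullMean <= 0) return(NA_real_)
  ablationMean / fullMean
}

#' Filter ablation records by fold frequency
#'
#' Because constant first-step models are dropped per fold, an ablation
#' subset may be computable in only some folds. Records computed in fewer
#' than `minFolds` folds are excluded from analysis.
#'
#' @param records data.frame with a `foldCount` column (see
#'   [ablationTable()]).
#' @param minFolds minimum number of folds, default 5.
#' @return The retained rows of `records`.
#' @export
filterByFoldFrequency <- function(records, minFolds = 5L) {
  records[records$foldCount >= minFolds, , drop = FALSE]
}

#' Ablation heatmap matrix
#'
#' Reshapes ablation records into the algorithms-by-subsets matrix of
#' relative performances used for heatmap display, rows in registry
#' order and columns in canonical enumeration order.
#'
#' @param records ablation data.frame (see [ablationTable()]), typically
#'   after [filterByFoldFrequency()].
#' @return Numeric matrix, algorithms x retained subsets.
#' @export
ablationMatrix <- function(records) {
  algs <- intersect(algorithmRegistry()$id, unique(records$algorithm))
  subsets <- unique(records$subset[order(records$subsetOrder)])
  m <- matrix(NA_real_, length(algs), length(subsets),
              dimnames = list(algs, subsets))
  for (i in seq_len(nrow(records)))
    m[records$algorithm[i], records$subset[i]] <-
      records$relPerformance[i]
  m
}

#' Aggregate cross-fold biomarker stability
#'
#' Counts, for every discrete feature found significant in at least one
#' cross-validation fold, how often it is recovered across the folds;
#' features identified in at least `minHits` of the folds are flagged
#' stable. The effect direction (sensitivity when the responder fraction
#' is higher with the feature present, resistance otherwise) and the mean
#' and standard deviation of the relative importance assigned to the
#' feature's source first-step model by the second-step algorithms are
#' attached.
#'
#' @param featureTables list (one per fold) of data.frames with columns
#'   `dataType`, `feature`, `p`, `direction`.
#' @param importanceTable data.frame with columns `fold`, `slot`,
#'   `importance`: per-fold mean relative importance of each first-step
#'   model across the weight-producing algorithms.
#' @param nFolds total number of folds (default 10).
#' @param minHits stability threshold, default 7 (of 10).
#' @return data.frame with one row per feature: `dataType`, `feature`,
#'   `foldHits`, `stable`, `direction`, `meanImportance`, `sdImportance`.
#' @export
aggregateStability <- function(featureTables, importanceTable,
                               nFolds = 10L, minHits = 7L) {
  all <- do.call(rbind, featureTables)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(dataType = character(), feature = character(),
                      foldHits = integer(), stable = logical(),
                      direction = character(), meanImportance = numeric(),
                      sdImportance = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(all$dataType, all$feature, sep = "\r")
  hits <- table(key)
  uniq <- names(hits)
  dataType <- sub("\r.*$", "", uniq)
  feature <- sub("^.*\r", "", uniq)
  direction <- vapply(uniq, function(k) {
    d <- all$direction[key == k]
    names(sort(table(d), decreasing = TRUE))[1L]
  }, character(1L))
  impOf <- function(slot) {
    v <- importanceTable$importance[importanceTable$slot == slot]
    v <- v[is.finite(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }
  imp <- vapply(dataType, impOf, numeric(2L))
  out <- data.frame(dataType = dataType, feature = feature,
                    foldHits = as.integer(hits[uniq]),
                    stable = as.integer(hits[uniq]) >= minHits,
                    direction = unname(direction),
                    meanImportance = unname(imp["mean", ]),
                    sdImportance = unname(imp["sd", ]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$foldHits, out$dataType, out$feature), , drop = FALSE]
}
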