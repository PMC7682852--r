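#' @import methods
NULL

#' Canonical data-type (layer) order
#'
#' All per-layer results in this package are reported in a fixed order:
#' somatic mutation, copy-number variation, hypermethylation, tissue
#' descriptors, pathway activation, gene expression.
#'
#' @return Character vector of the six layer names.
#' @export
canonicalLayers <- function() {
  c("mutation", "cnv", "methylation", "tissue", "pathway", "expression")
}

.dtypeClasses <- c("binary", "ternary", "onehot", "continuous")

# Returns NULL when values satisfy the domain of the declared class,
# otherwise a message naming the first offending cell.
.featureDomainProblem <- function(values, dtypeClass) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    return("matrix must carry cell-line row names and feature column names")
  if (anyDuplicated(rownames(values)))
    return(sprintf("duplicate cell-line identifier '%s'",
                   rownames(values)[duplicated(rownames(values))][1L]))
  if (anyDuplicated(colnames(values)))
    return(sprintf("duplicate feature name '%s'",
                   colnames(values)[duplicated(colnames(values))][1L]))
  offending <- function(bad) {
    idx <- which(bad, arr.ind = TRUE)[1L, , drop = TRUE]
    sprintf("value %s at cell line '%s', feature '%s'",
            format(values[idx[1L], idx[2L]]),
            rownames(values)[idx[1L]], colnames(values)[idx[2L]])
  }
  switch(dtypeClass,
    binary = {
      bad <- is.na(values) | !(values %in% c(0, 1))
      if (any(bad)) return(paste("binary matrix contains out-of-domain",
                                 offending(bad)))
      NULL
    },
    ternary = {
      bad <- is.na(values) | !(values %in% c(-1, 0, 1))
      if (any(bad)) return(paste("ternary matrix contains out-of-domain",
                                 offending(bad)))
      NULL
    },
    onehot = {
      bad <- is.na(values) | !(values %in% c(0, 1))
      if (any(bad)) return(paste("one-hot matrix contains out-of-domain",
                                 offending(bad)))
      rs <- rowSums(values)
      if (any(rs != 1))
        return(sprintf("one-hot row '%s' sums to %s, expected exactly 1",
                       rownames(values)[which(rs != 1)[1L]],
                       format(rs[which(rs != 1)[1L]])))
      NULL
    },
    continuous = {
      bad <- !is.finite(values)
      if (any(bad)) return(paste("continuous matrix contains non-finite",
                                 offending(bad)))
      NULL
    },
    sprintf("unknown dtype class '%s'", dtypeClass))
}

#' A validated cell-line-by-feature matrix
#'
#' Thin S4 wrapper around a numeric matrix with a declared domain class:
#' `binary` ({0,1}, e.g. somatic mutation or hypermethylation calls),
#' `ternary` ({-1,0,1}, copy-number aberrations), `onehot` (tissue
#' membership, rows sum to one) or `continuous` (expression, pathway
#' scores). Validity enforces the domain and uniqueness of identifiers.
#'
#' @slot values numeric matrix, cell lines in rows, features in columns.
#' @slot dtypeClass one of `"binary"`, `"ternary"`, `"onehot"`,
#'   `"continuous"`.
#'
#' @export
setClass("FeatureMatrix",
         representation(values = "matrix", dtypeClass = "character"))

setValidity("FeatureMatrix", function(object) {
  if (length(object@dtypeClass) != 1L ||
      !object@dtypeClass %in% .dtypeClasses)
    return(sprintf("dtypeClass must be one of %s",
                   paste(.dtypeClasses, collapse = ", ")))
  problem <- .featureDomainProblem(object@values, object@dtypeClass)
  if (!is.null(problem)) problem else TRUE
})

#' Aligned multi-omics dataset for one drug
#'
#' Holds up to six feature layers (in canonical order, absent layers are
#' `NULL`) together with a continuous dose-response AUC vector, all
#' restricted to one identical, lexicographically ordered cell-line set.
#' Lower AUC means higher sensitivity.
#'
#' @slot layers named list of [FeatureMatrix-class] objects or `NULL`,
#'   names exactly `canonicalLayers()`.
#' @slot response named numeric vector of dose-response AUC values.
#' @slot drugLabel single character identifier of the drug.
#'
#' @export
setClass("OmicsDataset",
         representation(layers = "list", response = "numeric",
                        drugLabel = "character"))

setValidity("OmicsDataset", function(object) {
  if (!identical(names(object@layers), canonicalLayers()))
    return("layers must be named exactly by canonicalLayers(), in order")
  ids <- names(object@response)
  if (is.null(ids) || anyDuplicated(ids))
    return("response must be named by unique cell-line identifiers")
  if (any(!is.finite(object@response)))
    return("response must be finite for every aligned cell line")
  for (nm in canonicalLayers()) {
    lay <- object@layers[[nm]]
    if (is.null(lay)) next
    if (!is(lay, "FeatureMatrix"))
      return(sprintf("layer '%s' is not a FeatureMatrix", nm))
    if (!identical(rownames(lay@values), ids))
      return(sprintf("layer '%s' cell-line ordering differs from response",
                     nm))
  }
  TRUE
})

#' Cross-validation fold partition
#'
#' Stratified assignment of modelled (non-excluded) cell lines to test
#' folds. Excluded cell lines carry an `NA` assignment.
#'
#' @slot nFolds number of folds (default pipeline uses 10).
#' @slot assignments named integer vector of fold indices, `NA` for
#'   cell lines excluded from modelling.
#' @slot seed integer seed the assignment was drawn with.
#'
#' @export
setClass("FoldPartition",
         representation(nFolds = "integer", assignments = "integer",
                        seed = "integer"))

setValidity("FoldPartition", function(object) {
  a <- object@assignments[!is.na(object@assignments)]
  if (length(a) && (min(a) < 1L || max(a) > object@nFolds))
    return("fold assignments out of range")
  if (length(a)) {
    sizes <- tabulate(a, nbins = object@nFolds)
    if (max(sizes) - min(sizes) > 1L)
      return("fold sizes differ by more than 1")
  }
  TRUE
})

#' Discrete first-step cluster model
#'
#' Predictor built on one discrete data type: cell lines sharing the same
#' presence/absence pattern over the significant, non-redundant features
#' form a cluster, and the cluster's mean binarized responsiveness is the
#' prediction for any cell line matching that pattern. With no significant
#' feature the model collapses to a single trivial cluster with a constant
#' prediction.
#'
#' @slot dataType layer name the model was fitted on.
#' @slot relevant data.frame of all significant features (redundant ones
#'   included) with columns `feature`, `p`, `nPresent`, `direction`,
#'   `redundant`.
#' @slot nonredundant character vector of the pruned feature set actually
#'   used for clustering, ordered by ascending p-value.
#' @slot redundancyMap named character vector mapping each discarded
#'   redundant feature to the kept feature sharing its pattern.
#' @slot clusters data.frame with `pattern`, `n` and `prediction` (mean
#'   binarized responsiveness) per non-empty training cluster.
#' @slot states numeric matrix (clusters x features) of representative
#'   feature states per cluster; for ternary data the modal non-zero state.
#' @slot fallback training-set mean binarized responsiveness, used for
#'   test patterns unseen in training.
#' @slot cutoff accuracy-optimal threshold used to binarize the model's
#'   own continuous output.
#' @slot constant `TRUE` for the trivial single-cluster model.
#'
#' @export
setClass("ClusterModel",
         representation(dataType = "character", relevant = "data.frame",
                        nonredundant = "character",
                        redundancyMap = "character", clusters = "data.frame",
                        states = "matrix", fallback = "numeric",
                        cutoff = "numeric", constant = "logical"))

setValidity("ClusterModel", function(object) {
  if (nrow(object@clusters)) {
    pr <- object@clusters$prediction
    if (any(pr < 0 | pr > 1)) return("cluster predictions must lie in [0,1]")
    n <- length(object@nonredundant)
    if (object@dataType == "tissue") {
      if (nrow(object@clusters) > n + 1L)
        return("tissue model must have at most n+1 clusters")
    } else if (nrow(object@clusters) > 2^n) {
      return("cluster count exceeds 2^n")
    }
  }
  TRUE
})

#' Continuous first-step model
#'
#' Linear regression of the binarized response on either the leading
#' principal-component scores of basal gene expression or on the pathway
#' activation scores, with min-max output normalization to [0,1] and an
#' accuracy-optimal binarization cutoff, all derived from training cells
#' only.
#'
#' @slot dataType `"expression"` or `"pathway"`.
#' @slot center training feature means used for projection/centering.
#' @slot loadings principal-component loadings (0-column matrix for the
#'   pathway model, which regresses on the raw scores).
#' @slot coefficients regression coefficients, intercept first.
#' @slot coefPvalues per-coefficient two-sided p-values.
#' @slot bounds training min/max of the raw prediction, the normalization
#'   interval.
#' @slot cutoff binarization threshold on the normalized scale.
#' @slot nComponents number of principal components used.
#' @slot constant `TRUE` when the raw training prediction was constant
#'   (model excluded downstream).
#'
#' @export
setClass("ContinuousFirstStepModel",
         representation(dataType = "character", center = "numeric",
                        loadings = "matrix", coefficients = "numeric",
                        coefPvalues = "numeric", bounds = "numeric",
                        cutoff = "numeric", nComponents = "integer",
                        constant = "logical"))

#' Integrated second-step model
#'
#' One of the thirteen registry algorithms fitted on the non-constant
#' first-step output vectors (z-scored on the training fold so that
#' extracted weights are comparable across input slots).
#'
#' @slot algorithmId registry identifier, see [algorithmRegistry()].
#' @slot inputSlots ordered names of the surviving first-step inputs.
#' @slot fit opaque fitted object of the underlying algorithm.
#' @slot center,scale standardization parameters from the training fold.
#' @slot bounds,cutoff output normalization interval and accuracy-optimal
#'   threshold (score-producing algorithms only).
#' @slot usesScore `FALSE` for the hard-label naive Bayes classifier.
#' @slot constant `TRUE` when the fitted model emits a constant score.
#' @slot fallbackClass majority training class, used when `constant` or
#'   when the fit failed to converge.
#' @slot converged `FALSE` when fitting failed and the fallback applies.
#'
#' @export
setClass("IntegrationModel",
         representation(algorithmId = "character", inputSlots = "character",
                        fit = "ANY", center = "numeric", scale = "numeric",
                        bounds = "numeric", cutoff = "numeric",
                        usesScore = "logical", constant = "logical",
                        fallbackClass = "numeric", converged = "logical"))

#' Result bundle of a two-step modelling run
#'
#' Container for everything [runTwoStep()] computes for one drug: the CV
#' partition, per-fold first- and second-step models, prediction vectors,
#' metric tables, importances, ablation records and the cross-fold
#' stability report. Use the accessors ([metricsTable()],
#' [ablationTable()], [stabilityTable()], [importanceTable()],
#' [predictionsTable()]) rather than reaching into `@results`.
#'
#' @slot drugLabel drug identifier.
#' @slot config the configuration list the run was executed with.
#' @slot partition [FoldPartition-class] used.
#' @slot results named list of result components.
#'
#' @export
setClass("TwoStepRun",
         representation(drugLabel = "character", config = "list",
                        partition = "FoldPartition", results = "list"))
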