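#' Align feature layers and a response vector into one dataset
#'
#' Intersects the cell-line identifiers of all provided layers with the
#' cell lines that carry a (non-missing) response for the chosen drug,
#' orders the intersection lexicographically (C locale, so runs are
#' reproducible independent of input file order) and reorders every layer
#' identically. Counts of dropped cell lines are reported per source.
#'
#' @param matrices named list of [FeatureMatrix-class] objects; names must
#'   be a subset of `canonicalLayers()`. Layers may be absent: the routine
#'   then runs on the remainder.
#' @param response either a named numeric vector of dose-response AUC
#'   values or a cell-line-by-drug matrix (see [readResponseTable()]).
#' @param drug drug column name or 1-based index when `response` is a
#'   matrix; used as the dataset label otherwise.
#' @param verbose report dropped counts via `message()`.
#'
#' @return An [OmicsDataset-class].
#' @examples
#' mut <- FeatureMatrix(matrix(c(0, 1, 1, 0), 2, 2,
#'   dimnames = list(c("A", "B"), c("g1", "g2"))), "binary")
#' alignDataset(list(mutation = mut), c(A = 0.4, B = 0.9, C = 0.5),
#'              drug = "ex", verbose = FALSE)
#' @export
alignDataset <- function(matrices, response, drug = "drug", verbose = TRUE) {
  if (!length(matrices))
    .validationError("at least one feature matrix is required")
  if (is.null(names(matrices)) ||
      !all(names(matrices) %in% canonicalLayers()))
    .validationError(sprintf("layer names must be among: %s",
                             paste(canonicalLayers(), collapse = ", ")))
  if (anyDuplicated(names(matrices)))
    .validationError("duplicate layer names")
  if (is.matrix(response) || is.data.frame(response)) {
    response <- as.matrix(response)
    if (is.character(drug) && !drug %in% colnames(response))
      .validationError(sprintf("drug '%s' not found in response table", drug))
    vec <- response[, drug]
    names(vec) <- rownames(response)
    if (is.numeric(drug)) drug <- colnames(response)[drug]
    response <- vec
  }
  if (is.null(names(response)))
    .validationError("response must be named by cell-line identifiers")
  keep <- names(response)[is.finite(response)]
  nDroppedResp <- length(response) - length(keep)
  common <- Reduce(intersect,
                   lapply(matrices, function(m) rownames(featureValues(m))),
                   keep)
  if (!length(common))
    .validationError("empty intersection of cell-line identifiers")
  common <- sort(common, method = "radix")
  if (verbose) {
    if (nDroppedResp)
      message(sprintf("response: dropped %d cell line(s) with missing values",
                      nDroppedResp))
    for (nm in names(matrices)) {
      d <- nrow(featureValues(matrices[[nm]])) - length(common)
      if (d > 0) message(sprintf("%s: dropped %d cell line(s) outside the %d-line intersection",
                                 nm, d, length(common)))
    }
  }
  layers <- stats::setNames(vector("list", 6L), canonicalLayers())
  for (nm in names(matrices)) {
    fm <- matrices[[nm]]
    layers[[nm]] <- new("FeatureMatrix",
                        values = featureValues(fm)[common, , drop = FALSE],
                        dtypeClass = dtypeClass(fm))
  }
  new("OmicsDataset", layers = layers, response = response[common],
      drugLabel = as.character(drug))
}

#' @rdname OmicsDataset-class
#' @param object,x an `OmicsDataset`.
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' @rdname OmicsDataset-class
#' @export
setMethod("response", "OmicsDataset", function(x) x@response)

#' @rdname OmicsDataset-class
#' @export
setGeneric("drugLabel", function(x) standardGeneric("drugLabel"))

#' @rdname OmicsDataset-class
#' @export
setMethod("drugLabel", "OmicsDataset", function(x) x@drugLabel)

#' @rdname OmicsDataset-class
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname OmicsDataset-class
#' @export
setMethod("cellLines", "OmicsDataset", function(x) names(x@response))

#' @rdname OmicsDataset-class
#'   order.
#' @export
setGeneric("presentLayers", function(x) standardGeneric("presentLayers"))

#' @rdname OmicsDataset-class
#' @export
setMethod("presentLayers", "OmicsDataset", function(x) {
  canonicalLayers()[!vapply(x@layers, is.null, logical(1L))]
})

#' @rdname OmicsDataset-class
#' @param layer layer name.
#' @export
setGeneric("layerMatrix", function(x, layer) standardGeneric("layerMatrix"))

#' @rdname OmicsDataset-class
#' @export
setMethod("layerMatrix", "OmicsDataset", function(x, layer) {
  layer <- match.arg(layer, canonicalLayers())
  if (is.null(x@layers[[layer]]))
    .validationError(sprintf("layer '%s' is absent from this dataset", layer))
  featureValues(x@layers[[layer]])
})

setMethod("show", "OmicsDataset", function(object) {
  cat(sprintf("OmicsDataset for drug '%s': %d cell lines\n",
              object@drugLabel, length(object@response)))
  for (nm in canonicalLayers()) {
    lay <- object@layers[[nm]]
    if (is.null(lay)) {
      cat(sprintf("  %-12s absent\n", nm))
    } else {
      cat(sprintf("  %-12s %d features (%s)\n", nm,
                  ncol(featureValues(lay)), dtypeClass(lay)))
    }
  }
})
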