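#' Construct a FeatureMatrix
#'
#' Validates a cell-line-by-feature matrix against the domain of its
#' declared data-type class. Domain violations raise a typed
#' `twoStepValidationError` naming the offending cell.
#'
#' @param values numeric matrix with cell-line row names and feature
#'   column names.
#' @param dtypeClass `"binary"`, `"ternary"`, `"onehot"` or
#'   `"continuous"`.
#'
#' @return A [FeatureMatrix-class].
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2,
#'             dimnames = list(c("A", "B"), c("TP53", "BRAF")))
#' FeatureMatrix(m, "binary")
#' @export
FeatureMatrix <- function(values,
                          dtypeClass = c("binary", "ternary", "onehot",
                                         "continuous")) {
  dtypeClass <- match.arg(dtypeClass)
  values <- as.matrix(values)
  if (!is.numeric(values))
    .validationError("feature matrix values must be numeric")
  storage.mode(values) <- "double"
  problem <- .featureDomainProblem(values, dtypeClass)
  if (!is.null(problem)) .validationError(problem)
  new("FeatureMatrix", values = values, dtypeClass = dtypeClass)
}

#' @describeIn FeatureMatrix matrix of values.
#' @param object,x a `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn FeatureMatrix declared domain class.
#' @export
setGeneric("dtypeClass", function(x) standardGeneric("dtypeClass"))

#' @rdname FeatureMatrix
#' @export
setMethod("dtypeClass", "FeatureMatrix", function(x) x@dtypeClass)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d cell lines x %d features\n",
              object@dtypeClass, nrow(object@values), ncol(object@values)))
})

.delimChar <- function(delim = c("tab", "comma")) {
  if (match.arg(delim, c("tab", "comma")) == "tab") "\t" else ","
}

#' Read a delimited feature matrix
#'
#' Expects a header row of feature names and a first column of cell-line
#' identifiers; remaining columns must be numeric and within the domain of
#' `dtypeClass`. Tab-separated by default, comma optionally; decimal point
#' only.
#'
#' @param path file path.
#' @param dtypeClass declared domain class, see [FeatureMatrix()].
#' @param delim `"tab"` (default) or `"comma"`.
#'
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path, dtypeClass, delim = "tab") {
  sep <- .delimChar(delim)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = ""),
    error = function(e) .validationError(
      sprintf("malformed table '%s': %s", path, conditionMessage(e))))
  if (ncol(df) < 2L)
    .validationError(sprintf(
      "malformed table '%s': need an identifier column plus features", path))
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1L))
  if (any(nonnum))
    .validationError(sprintf("malformed table '%s': column '%s' is not numeric",
                             path, colnames(vals)[nonnum][1L]))
  m <- as.matrix(vals)
  rownames(m) <- ids
  FeatureMatrix(m, dtypeClass)
}

#' Write a feature matrix
#'
#' Inverse of [readFeatureMatrix()]: values are serialized at full double
#' precision so that a write/reload round trip is exact.
#'
#' @param x a [FeatureMatrix-class] (or plain named matrix).
#' @param path output file path.
#' @param delim `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(x, path, delim = "tab") {
  values <- if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
  sep <- .delimChar(delim)
  out <- data.frame(cell_line = rownames(values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(values)))
    out[[colnames(values)[j]]] <- sprintf("%.17g", values[, j])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell-line response table
#'
#' A delimited table with a cell-line identifier column and one column per
#' drug; empty fields and `NA` denote missing response measurements (the
#' affected cell lines are dropped during alignment).
#'
#' @param path file path.
#' @param delim `"tab"` or `"comma"`.
#' @return Numeric matrix, cell lines in rows, drugs in columns.
#' @export
readResponseTable <- function(path, delim = "tab") {
  sep <- .delimChar(delim)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  if (ncol(df) < 2L)
    .validationError(sprintf(
      "malformed table '%s': need an identifier column plus drugs", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    .validationError(sprintf("duplicate cell-line identifier '%s' in '%s'",
                             ids[duplicated(ids)][1L], path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
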