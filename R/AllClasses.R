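#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' OliveIndexSet: colorimetric index features with sample metadata
#'
#' An \linkS4class{SummarizedExperiment} holding the 35 RGB colorimetric
#' indexes (rows of the \code{"indexes"} assay) for a set of fruit samples
#' (columns). Sample metadata (cultivar, sampling time, measured oil and
#' phenol concentrations, raw channel means) lives in \code{colData};
#' \code{metadata()} records the formula dialect used and the per-index count
#' of undefined (degenerate-denominator) values.
#'
#' @seealso [buildFeatureTable()], [indexMatrix()], [undefinedCounts()]
#' @export
setClass("OliveIndexSet", contains = "SummarizedExperiment")

setValidity("OliveIndexSet", function(object) {
  if (!"indexes" %in% SummarizedExperiment::assayNames(object))
    return("assay 'indexes' is missing")
  if (!identical(rownames(object), indexNames()))
    return("assay rows must be the 35 colorimetric indexes in registry order")
  TRUE
})

#' ReductionResult: PCA or sparse-PCA decomposition of a feature matrix
#'
#' Holds loadings (features x components), scores (samples x components), the
#' explained-variance fraction of each retained component, and for sparse fits
#' the per-component cardinality target (NNZL) and the set of variables with a
#' nonzero loading in any component.
#'
#' @slot loadings numeric matrix, features x retained components.
#' @slot scores numeric matrix, samples x retained components.
#' @slot explainedVariance fraction of total variance per retained component
#'   (adjusted explained variance for sparse fits).
#' @slot allFractions explained fractions of all components (PCA only).
#' @slot kRetained number of retained components.
#' @slot method "pca" or "spca".
#' @slot nnzl integer cardinality targets per component (sparse fits).
#' @slot retainedVariables variables with nonzero loading in any sparse
#'   component (each counted once).
#' @slot iterations,converged alternation diagnostics (sparse fits).
#' @seealso [fitPCA()], [fitSPCA()], [selectVariables()]
#' @export
setClass("ReductionResult",
  representation(
    loadings = "matrix",
    scores = "matrix",
    explainedVariance = "numeric",
    allFractions = "numeric",
    kRetained = "integer",
    method = "character",
    nnzl = "integer",
    retainedVariables = "character",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("ReductionResult", function(object) {
  k <- object@kRetained
  if (ncol(object@loadings) != k) return("loadings must have kRetained columns")
  if (ncol(object@scores) != k) return("scores must have kRetained columns")
  if (length(object@explainedVariance) != k)
    return("explainedVariance must have one entry per retained component")
  if (!object@method %in% c("pca", "spca")) return("method must be 'pca' or 'spca'")
  if (object@method == "spca") {
    if (length(object@nnzl) != k) return("nnzl must have one entry per component")
    nz <- colSums(abs(object@loadings) > 0)
    if (any(nz > object@nnzl)) return("cardinality constraint violated")
  }
  TRUE
})

#' RpropNet: single-hidden-layer regression network trained by Rprop+
#'
#' Weight matrices include the bias as their first row. Hidden units use the
#' logistic activation; the single output unit is linear on the min-max scaled
#' target, and predictions are mapped back to original units.
#'
#' @slot W1 (n_inputs + 1) x n_hidden input-to-hidden weights (row 1 = bias).
#' @slot W2 (n_hidden + 1) x 1 hidden-to-output weights (row 1 = bias).
#' @slot spec the training specification (see [networkSpec()]).
#' @slot yRange min and max of the training targets (the scaling constants).
#' @slot errorTrace summed-squared-error at each epoch.
#' @slot converged did the gradient norm reach the stopping threshold.
#' @slot epochs number of epochs run.
#' @seealso [trainBPNN()], [predict,RpropNet-method]
#' @export
setClass("RpropNet",
  representation(
    W1 = "matrix",
    W2 = "matrix",
    spec = "list",
    yRange = "numeric",
    errorTrace = "numeric",
    converged = "logical",
    epochs = "integer"
  )
)

setValidity("RpropNet", function(object) {
  s <- object@spec
  if (nrow(object@W1) != s$n_inputs + 1L || ncol(object@W1) != s$n_hidden)
    return("W1 shape inconsistent with spec")
  if (nrow(object@W2) != s$n_hidden + 1L || ncol(object@W2) != 1L)
    return("W2 shape inconsistent with spec")
  if (length(object@yRange) != 2L) return("yRange must be length 2")
  TRUE
})

#' @describeIn ReductionResult loadings matrix accessor
#' @param object a \code{ReductionResult}
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))
#' @rdname ReductionResult-class
#' @export
setMethod("loadings", "ReductionResult", function(object) object@loadings)

#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname ReductionResult-class
#' @export
setMethod("scores", "ReductionResult", function(object) object@scores)

#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname ReductionResult-class
#' @export
setMethod("explainedVariance", "ReductionResult", function(object) object@explainedVariance)

#' @export
setGeneric("kRetained", function(object) standardGeneric("kRetained"))
#' @rdname ReductionResult-class
#' @export
setMethod("kRetained", "ReductionResult", function(object) object@kRetained)

#' @export
setGeneric("nnzl", function(object) standardGeneric("nnzl"))
#' @rdname ReductionResult-class
#' @export
setMethod("nnzl", "ReductionResult", function(object) object@nnzl)

setMethod("show", "ReductionResult", function(object) {
  cat(sprintf(
    "%s decomposition: %d feature(s), %d retained component(s)\n",
    toupper(object@method), nrow(object@loadings), object@kRetained
  ))
  cat(sprintf(
    "explained variance fraction: %s (cumulative %.3f)\n",
    paste(sprintf("%.3f", object@explainedVariance), collapse = ", "),
    sum(object@explainedVariance)
  ))
  if (object@method == "spca")
    cat(sprintf(
      "nnzl: %s; %d variable(s) with nonzero loading\n",
      paste(object@nnzl, collapse = ", "), length(object@retainedVariables)
    ))
})

setMethod("show", "RpropNet", function(object) {
  s <- object@spec
  cat(sprintf(
    "RpropNet: %d-%d-1 topology, logistic hidden / linear output\n",
    s$n_inputs, s$n_hidden
  ))
  cat(sprintf(
    "trained %d epoch(s), %s (final SSE %.4g)\n", object@epochs,
    if (object@converged) "converged" else "stopped at max_epochs",
    object@errorTrace[length(object@errorTrace)]
  ))
})

setMethod("show", "OliveIndexSet", function(object) {
  callNextMethod()
  ud <- S4Vectors::metadata(object)$undefined_counts
  cat(sprintf(
    "dialect: %s; undefined index values: %d\n",
    S4Vectors::metadata(object)$dialect %||% "?", sum(ud %||% 0)
  ))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
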