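#' Accessors for the core classes
#'
#' \code{drugNames}/\code{targetNames} return the identifier vectors,
#' \code{nDrugs}/\code{nTargets} their lengths, \code{entityNames} the shared
#' namespace of a similarity matrix, and \code{simDiagonal} its declared
#' diagonal convention.
#'
#' @param x an object of one of the package classes
#' @return character vectors of identifiers, integer counts, or the diagonal
#'   convention string
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))
#' @rdname accessors
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))
#' @rdname accessors
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))
#' @rdname accessors
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))
#' @rdname accessors
#' @export
setGeneric("simDiagonal", function(x) standardGeneric("simDiagonal"))

#' @rdname accessors
#' @export
setMethod("drugNames", "InteractionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("targetNames", "InteractionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("nDrugs", "InteractionMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nTargets", "InteractionMatrix", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("drugNames", "DatasetBundle", function(x) drugNames(x@interactions))
#' @rdname accessors
#' @export
setMethod("targetNames", "DatasetBundle", function(x) targetNames(x@interactions))
#' @rdname accessors
#' @export
setMethod("drugNames", "HeteroGraph", function(x) drugNames(x@dtEdges))
#' @rdname accessors
#' @export
setMethod("targetNames", "HeteroGraph", function(x) targetNames(x@dtEdges))
#' @rdname accessors
#' @export
setMethod("entityNames", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("simDiagonal", "SimilarityMatrix", function(x) x@diagonal)

#' Matrix views of package objects
#'
#' @param x an \linkS4class{InteractionMatrix} or
#'   \linkS4class{SimilarityMatrix}
#' @param ... ignored
#' @return the underlying numeric matrix (a copy)
#' @export
setMethod("as.matrix", "InteractionMatrix", function(x, ...) x@values)
#' @rdname as.matrix-InteractionMatrix-method
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

setMethod("show", "InteractionMatrix", function(object) {
  v <- object@values
  cat(sprintf("InteractionMatrix: %d drugs x %d targets, %d known DTIs\n",
              nrow(v), ncol(v), sum(v)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[row(v) != col(v)]
  cat(sprintf(
    "SimilarityMatrix: %d entities, diagonal '%s', off-diag range [%.3f, %.3f]\n",
    nrow(v), object@diagonal, min(off), max(off)))
})

setMethod("show", "DatasetBundle", function(object) {
  st <- datasetStatistics(object)
  cat(sprintf(paste0(
    "DatasetBundle: %d drugs, %d targets, %d known / %d unknown DTIs ",
    "(sparsity %.3f)\n  drug views: %s\n  target views: %s\n"),
    st$nDrugs, st$nTargets, st$known, st$unknown, st$sparsity,
    paste(names(object@drugSims), collapse = ", "),
    paste(names(object@targetSims), collapse = ", ")))
})

setMethod("show", "HeteroGraph", function(object) {
  dd <- object@ddWeights@values; tt <- object@ttWeights@values
  dt <- object@dtEdges@values
  cat(sprintf(
    "HeteroGraph: %d drug + %d target nodes; %d DD, %d TT, %d DT edges\n",
    nrow(dd), nrow(tt), sum(dd[upper.tri(dd)] > 0),
    sum(tt[upper.tri(tt)] > 0), sum(dt)))
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf("PairDataset: %d pairs (%d positive), %d features\n",
              nrow(object@pairs), sum(object@labels), ncol(object@features)))
})

setMethod("show", "MetricsReport", function(object) {
  s <- object@summary
  cat(sprintf("MetricsReport over %d folds\n", nrow(object@folds)))
  cat(sprintf("  AUPR %.4f +/- %.4f   AUC %.4f +/- %.4f   ER %.4f\n",
              s$meanAUPR, s$sdAUPR, s$meanAUC, s$sdAUC, s$er))
  if (!is.null(s$map) && !is.na(s$map))
    cat(sprintf("  MAP  %.4f\n", s$map))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: drug views [%s]; target views [%s]; %d round(s)\n",
    paste(object@selectedDrugViews, collapse = ", "),
    paste(object@selectedTargetViews, collapse = ", "),
    length(object@trace)))
})

#' Per-pair features and labels of a PairDataset
#' @param x a \linkS4class{PairDataset}
#' @return \code{pairFeatures}: the feature matrix; \code{pairLabels}: the
#'   0/1 label vector; \code{pairIndex}: the (drug, target) data.frame
#' @export
pairFeatures <- function(x) x@features
#' @rdname pairFeatures
#' @export
pairLabels <- function(x) x@labels
#' @rdname pairFeatures
#' @export
pairIndex <- function(x) x@pairs

#' Per-fold metrics of a MetricsReport
#' @param x a \linkS4class{MetricsReport}
#' @return \code{foldMetrics}: data.frame of per-fold AUPR/AUC/MAP;
#'   \code{metricsSummary}: named list of aggregates
#' @export
foldMetrics <- function(x) x@folds
#' @rdname foldMetrics
#' @export
metricsSummary <- function(x) x@summary
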