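#' @import methods
NULL

.TOL_SYM <- 1e-9
.TOL_RANGE <- 1e-9

#' InteractionMatrix: binary drug-target adjacency
#'
#' An n x m binary matrix over n drugs (rows) and m targets (columns).
#' Entry (i, j) is 1 when drug i is known to interact with target j and 0
#' otherwise. Row and column names carry the drug and target identifiers,
#' which are treated as opaque strings.
#'
#' @slot values binary numeric matrix with unique row/column names
#' @export
setClass("InteractionMatrix", representation(values = "matrix"))

setValidity("InteractionMatrix", function(object) {
  v <- object@values
  if (nrow(v) < 1L || ncol(v) < 1L)
    return("interaction matrix needs at least one drug and one target")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("interaction matrix must carry drug (row) and target (column) names")
  if (anyDuplicated(rownames(v))) return("duplicate drug identifiers")
  if (anyDuplicated(colnames(v))) return("duplicate target identifiers")
  if (!all(v %in% c(0, 1))) return("interaction entries must be 0 or 1")
  TRUE
})

#' Construct an InteractionMatrix
#'
#' @param values numeric matrix of 0/1 entries
#' @param drugIds,targetIds optional identifier vectors; default to the
#'   dimnames of \code{values}
#' @return an \linkS4class{InteractionMatrix}
#' @examples
#' InteractionMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("d1", "d2"), c("t1", "t2"))))
#' @export
InteractionMatrix <- function(values, drugIds = rownames(values),
                              targetIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(drugIds, targetIds)
  new("InteractionMatrix", values = values)
}

#' SimilarityMatrix: labeled square symmetric similarity
#'
#' A k x k symmetric matrix with entries in [0, 1] over one entity namespace
#' (all drugs or all targets). The diagonal follows a declared convention:
#' \code{"unit"} (all ones, kernel style) or \code{"zero"} (no self-loops,
#' graph style).
#'
#' @slot values symmetric numeric matrix, entries in [0, 1]
#' @slot diagonal \code{"unit"} or \code{"zero"}
#' @export
setClass("SimilarityMatrix",
         representation(values = "matrix", diagonal = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("similarity matrix must be square")
  if (is.null(rownames(v))) return("similarity matrix must carry entity names")
  if (anyDuplicated(rownames(v))) return("duplicate entity identifiers")
  if (!identical(rownames(v), colnames(v)))
    return("row and column names must match")
  if (max(abs(v - t(v))) > .TOL_SYM) return("matrix is not symmetric")
  if (min(v) < -.TOL_RANGE || max(v) > 1 + .TOL_RANGE)
    return("similarity entries must lie in [0, 1]")
  if (!object@diagonal %in% c("unit", "zero"))
    return("diagonal convention must be 'unit' or 'zero'")
  want <- if (object@diagonal == "unit") 1 else 0
  if (any(abs(diag(v) - want) > .TOL_RANGE))
    return(sprintf("diagonal must be all-%d under the '%s' convention",
                   want, object@diagonal))
  TRUE
})

#' Construct a SimilarityMatrix
#'
#' The diagonal is forced to the declared convention; off-diagonal entries
#' are clipped of numerical fuzz just outside [0, 1] (within 1e-9).
#'
#' @param values square numeric matrix
#' @param ids optional entity identifiers; default rownames
#' @param diagonal diagonal convention, \code{"unit"} or \code{"zero"}
#' @return a \linkS4class{SimilarityMatrix}
#' @export
SimilarityMatrix <- function(values, ids = rownames(values),
                             diagonal = c("unit", "zero")) {
  diagonal <- match.arg(diagonal)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, ids)
  values <- pmin(pmax(values, 0), 1)
  diag(values) <- if (diagonal == "unit") 1 else 0
  new("SimilarityMatrix", values = values, diagonal = diagonal)
}

#' DatasetBundle: interactions plus similarity views
#'
#' Holds one interaction matrix together with named collections of drug-drug
#' and target-target similarity views sharing its identifier spaces.
#'
#' @slot interactions an \linkS4class{InteractionMatrix}
#' @slot drugSims named list of drug-drug \linkS4class{SimilarityMatrix}
#' @slot targetSims named list of target-target \linkS4class{SimilarityMatrix}
#' @export
setClass("DatasetBundle",
         representation(interactions = "InteractionMatrix",
                        drugSims = "list", targetSims = "list"))

setValidity("DatasetBundle", function(object) {
  dn <- rownames(object@interactions@values)
  tn <- colnames(object@interactions@values)
  chk <- function(lst, ids, what) {
    if (length(lst) && is.null(names(lst)))
      return(sprintf("%s similarity views must be named", what))
    for (nm in names(lst)) {
      s <- lst[[nm]]
      if (!is(s, "SimilarityMatrix"))
        return(sprintf("%s view '%s' is not a SimilarityMatrix", what, nm))
      if (!identical(rownames(s@values), ids))
        return(sprintf("%s view '%s' does not share the bundle identifiers",
                       what, nm))
    }
    TRUE
  }
  ok <- chk(object@drugSims, dn, "drug")
  if (!isTRUE(ok)) return(ok)
  chk(object@targetSims, tn, "target")
})

#' Construct a DatasetBundle
#'
#' @param interactions an \linkS4class{InteractionMatrix}
#' @param drugSims,targetSims named lists of \linkS4class{SimilarityMatrix}
#' @return a \linkS4class{DatasetBundle}
#' @export
DatasetBundle <- function(interactions, drugSims = list(), targetSims = list()) {
  new("DatasetBundle", interactions = interactions,
      drugSims = drugSims, targetSims = targetSims)
}

#' HeteroGraph: tripartite weighted graph over drugs and targets
#'
#' The heterogeneous graph with three edge types: drug-drug similarity edges
#' (weights in (0, 1], zero diagonal), target-target similarity edges
#' (likewise), and drug-target interaction edges of weight exactly 1.
#' Instances stand for the embedding-input graph G, the fused-similarity
#' graph G1, or the cosine-similarity graph G2.
#'
#' @slot ddWeights drug-drug \linkS4class{SimilarityMatrix}, zero diagonal
#' @slot ttWeights target-target \linkS4class{SimilarityMatrix}, zero diagonal
#' @slot dtEdges \linkS4class{InteractionMatrix} of training interactions
#' @export
setClass("HeteroGraph",
         representation(ddWeights = "SimilarityMatrix",
                        ttWeights = "SimilarityMatrix",
                        dtEdges = "InteractionMatrix"))

setValidity("HeteroGraph", function(object) {
  if (object@ddWeights@diagonal != "zero" || object@ttWeights@diagonal != "zero")
    return("similarity layers of a HeteroGraph use the zero-diagonal convention")
  if (!identical(rownames(object@ddWeights@values),
                 rownames(object@dtEdges@values)))
    return("drug identifiers disagree between ddWeights and dtEdges")
  if (!identical(rownames(object@ttWeights@values),
                 colnames(object@dtEdges@values)))
    return("target identifiers disagree between ttWeights and dtEdges")
  TRUE
})

#' PairDataset: per-pair feature vectors and labels
#'
#' One row per (drug, target) pair; \code{features} may have zero columns for
#' a label-only skeleton. Labels are 1 for known interactions, 0 otherwise.
#'
#' @slot pairs data.frame with columns \code{drug}, \code{target}
#' @slot features numeric matrix, one row per pair, named columns
#' @slot labels integer vector of 0/1
#' @export
setClass("PairDataset",
         representation(pairs = "data.frame", features = "matrix",
                        labels = "integer"))

setValidity("PairDataset", function(object) {
  n <- nrow(object@pairs)
  if (!all(c("drug", "target") %in% colnames(object@pairs)))
    return("pairs must have 'drug' and 'target' columns")
  if (nrow(object@features) != n) return("features/pairs row mismatch")
  if (length(object@labels) != n) return("labels/pairs length mismatch")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (ncol(object@features) > 0 && is.null(colnames(object@features)))
    return("feature columns must be named")
  TRUE
})

#' Construct a PairDataset
#' @param pairs data.frame with \code{drug} and \code{target} columns
#' @param features numeric matrix (may have zero columns)
#' @param labels 0/1 vector
#' @return a \linkS4class{PairDataset}
#' @export
PairDataset <- function(pairs, features = matrix(numeric(0), nrow(pairs), 0),
                        labels) {
  new("PairDataset", pairs = pairs, features = as.matrix(features),
      labels = as.integer(labels))
}

#' MetricsReport: cross-validation performance summary
#'
#' Per-fold AUPR/AUC with their means and standard deviations, the error
#' rate ER = 1 - mean AUPR, and (when computed) the mean average precision
#' over drugs.
#'
#' @slot folds data.frame with columns \code{fold}, \code{aupr}, \code{auc},
#'   \code{map} (per-fold mean average precision, possibly \code{NA})
#' @slot summary named list of aggregate metrics
#' @export
setClass("MetricsReport",
         representation(folds = "data.frame", summary = "list"))

#' SelectionResult: outcome of forward similarity selection
#'
#' @slot selectedDrugViews,selectedTargetViews ordered character vectors
#' @slot trace list of per-round data.frames of candidate scores
#' @slot scores numeric vector of accepted-round evaluator scores
#' @export
setClass("SelectionResult",
         representation(selectedDrugViews = "character",
                        selectedTargetViews = "character",
                        trace = "list", scores = "numeric"))
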