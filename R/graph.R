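#' KNN sparsification of a similarity matrix
#'
#' Keeps, for every entity, its k largest off-diagonal similarities and zeroes
#' the rest; an entry survives when either endpoint nominates it (symmetric
#' union), which preserves symmetry. Ties at the k-th neighbour are all kept,
#' so the operation is deterministic and idempotent. Surviving values are
#' unchanged.
#'
#' @param S a \linkS4class{SimilarityMatrix}
#' @param k number of neighbours per entity, in [1, entities - 1]
#' @return a zero-diagonal \linkS4class{SimilarityMatrix}
#' @export
knnSparsify <- function(S, k) {
  v <- S@values
  n <- nrow(v)
  if (k < 1 || k > n - 1)
    stop(sprintf("k must be in [1, %d], got %s", n - 1, k))
  diag(v) <- 0
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    row <- v[i, ]
    pos <- which(row > 0)
    if (!length(pos)) next
    kth <- sort(row[pos], decreasing = TRUE)[min(k, length(pos))]
    keep[i, ] <- row >= kth & row > 0
  }
  keep <- keep | t(keep)
  v[!keep] <- 0
  SimilarityMatrix(v, ids = entityNames(S), diagonal = "zero")
}

#' Build the heterogeneous drug-target graph
#'
#' Assembles the tripartite weighted graph over n drug and m target nodes:
#' drug-drug similarity edges, target-target similarity edges (both with
#' zero diagonals; zero weights produce no edge), and drug-target
#' interaction edges of weight 1 taken from the training interactions.
#'
#' @param dd drug-drug \linkS4class{SimilarityMatrix}
#' @param tt target-target \linkS4class{SimilarityMatrix}
#' @param dtiTrain \linkS4class{InteractionMatrix} of training interactions
#' @return a \linkS4class{HeteroGraph}
#' @examples
#' toy <- makeWorkedToy()
#' buildHeteroGraph(toy@drugSims[[1]], toy@targetSims[[1]], toy@interactions)
#' @export
buildHeteroGraph <- function(dd, tt, dtiTrain) {
  if (!identical(entityNames(dd), drugNames(dtiTrain)))
    stop("drug identifiers of dd and dtiTrain disagree")
  if (!identical(entityNames(tt), targetNames(dtiTrain)))
    stop("target identifiers of tt and dtiTrain disagree")
  zd <- function(s) SimilarityMatrix(s@values, ids = entityNames(s),
                                     diagonal = "zero")
  new("HeteroGraph", ddWeights = zd(dd), ttWeights = zd(tt),
      dtEdges = dtiTrain)
}

#' Mask test-fold drug-target edges
#'
#' Returns a copy of the graph with the drug-target edges at the given pairs
#' removed; similarity weights are never touched, and masking an absent edge
#' is a no-op. Masking test positives before any graph-derived computation
#' is what keeps cross-validation leak-free.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @param mask data.frame with columns \code{drug}, \code{target}
#' @return a \linkS4class{HeteroGraph} with the masked edges zeroed
#' @export
maskTestEdges <- function(g, mask) {
  dt <- g@dtEdges@values
  if (nrow(mask)) {
    i <- match(mask$drug, rownames(dt))
    j <- match(mask$target, colnames(dt))
    if (anyNA(i) || anyNA(j))
      stop("mask references unknown drug or target identifiers")
    dt[cbind(i, j)] <- 0
  }
  new("HeteroGraph", ddWeights = g@ddWeights, ttWeights = g@ttWeights,
      dtEdges = InteractionMatrix(dt, rownames(dt), colnames(dt)))
}

#' Export a heterogeneous graph as an edge list
#'
#' @param g a \linkS4class{HeteroGraph}
#' @return data.frame with columns \code{node1}, \code{node2}, \code{weight},
#'   \code{edge_type} (\code{"DD"}, \code{"TT"} or \code{"DT"}); each
#'   undirected similarity edge appears once
#' @export
asEdgeList <- function(g) {
  simEdges <- function(s, type, prefix) {
    v <- s@values
    idx <- which(upper.tri(v) & v > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(node1 = paste0(prefix, rownames(v)[idx[, 1]]),
               node2 = paste0(prefix, colnames(v)[idx[, 2]]),
               weight = v[idx], edge_type = type)
  }
  dt <- g@dtEdges@values
  idx <- which(dt == 1, arr.ind = TRUE)
  dtEdges <- if (nrow(idx))
    data.frame(node1 = paste0("drug:", rownames(dt)[idx[, 1]]),
               node2 = paste0("target:", colnames(dt)[idx[, 2]]),
               weight = 1, edge_type = "DT") else NULL
  out <- rbind(simEdges(g@ddWeights, "DD", "drug:"),
               simEdges(g@ttWeights, "TT", "target:"), dtEdges)
  if (is.null(out))
    out <- data.frame(node1 = character(0), node2 = character(0),
                      weight = numeric(0), edge_type = character(0))
  rownames(out) <- NULL
  out
}
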