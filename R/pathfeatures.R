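#' Meta-path structures
#'
#' The six drug-to-target path structures of length two or three:
#' C1 (D-D-T), C2 (D-T-T), C3 (D-D-D-T), C4 (D-T-T-T), C5 (D-D-T-T) and
#' C6 (D-T-D-T). A concrete path must be simple: no node may appear twice.
#'
#' @format character vector of structure names
#' @export
pathStructures <- c("C1", "C2", "C3", "C4", "C5", "C6")

.STRUCT_LAYERS <- list(
  C1 = c("D", "D", "T"), C2 = c("D", "T", "T"),
  C3 = c("D", "D", "D", "T"), C4 = c("D", "T", "T", "T"),
  C5 = c("D", "D", "T", "T"), C6 = c("D", "T", "D", "T"))

#' Enumerate simple-path scores for one pair (brute-force oracle)
#'
#' Exhaustively lists every simple path of the given structure from drug
#' \code{d} to target \code{t} and returns the product of edge weights along
#' each. This is the reference the matrix-product implementations of
#' \code{\link{sumScoreMatrix}} and \code{\link{maxScoreMatrix}} are held
#' to; it is exponential in path length and meant for small graphs.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @param d,t drug and target identifiers
#' @param structure one of \code{pathStructures}
#' @return numeric vector of path products (empty when no path exists)
#' @examples
#' toy <- makeWorkedToy()
#' g <- buildHeteroGraph(toy@drugSims[[1]], toy@targetSims[[1]],
#'                       toy@interactions)
#' enumerateSimplePathScores(g, "d1", "t1", "C1")  # 0.5
#' @export
enumerateSimplePathScores <- function(g, d, t, structure) {
  structure <- match.arg(structure, pathStructures)
  dd <- g@ddWeights@values
  tt <- g@ttWeights@values
  dt <- g@dtEdges@values
  i <- match(d, drugNames(g)); j <- match(t, targetNames(g))
  if (is.na(i) || is.na(j)) stop("unknown drug or target identifier")
  nd <- nrow(dt); nt <- ncol(dt)
  scores <- numeric(0)
  add <- function(w) if (w > 0) scores[[length(scores) + 1L]] <<- w
  switch(structure,
    C1 = for (x in seq_len(nd)) if (x != i)
      add(dd[i, x] * dt[x, j]),
    C2 = for (u in seq_len(nt)) if (u != j)
      add(dt[i, u] * tt[u, j]),
    C3 = for (x in seq_len(nd)) if (x != i)
      for (y in seq_len(nd)) if (y != i && y != x)
        add(dd[i, x] * dd[x, y] * dt[y, j]),
    C4 = for (u in seq_len(nt)) if (u != j)
      for (v in seq_len(nt)) if (v != j && v != u)
        add(dt[i, u] * tt[u, v] * tt[v, j]),
    C5 = for (x in seq_len(nd)) if (x != i)
      for (u in seq_len(nt)) if (u != j)
        add(dd[i, x] * dt[x, u] * tt[u, j]),
    C6 = for (u in seq_len(nt)) if (u != j)
      for (x in seq_len(nd)) if (x != i)
        add(dt[i, u] * dt[x, u] * dt[x, j]))
  scores
}

# max-times matrix composition: C[i, j] = max_k A[i, k] * B[k, j]
.maxTimes <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (j in seq_len(ncol(b))) {
    col <- b[, j]
    nz <- which(col > 0)
    if (!length(nz)) next
    acc <- a[, nz[1]] * col[nz[1]]
    for (k in nz[-1]) acc <- pmax(acc, a[, k] * col[k])
    out[, j] <- acc
  }
  out
}

.zeroDiag <- function(m) { diag(m) <- 0; m }

#' Sum meta-path score matrix
#'
#' For every (drug, target) pair, the sum of edge-weight products over all
#' simple paths of the given structure, computed by chained matrix products
#' with closed-form corrections that remove non-simple walks: the zero
#' diagonals of the similarity layers kill immediate revisits, and the
#' remaining offenders (C3 walks d-x-d-t, C4 walks d-t-s-t, C6 walks reusing
#' the end drug or target) are subtracted by inclusion-exclusion. Equals
#' \code{\link{enumerateSimplePathScores}} summed per pair.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @param structure one of \code{pathStructures}
#' @return numeric drugs x targets matrix of Sum scores
#' @export
sumScoreMatrix <- function(g, structure) {
  structure <- match.arg(structure, pathStructures)
  dd <- .zeroDiag(g@ddWeights@values)
  tt <- .zeroDiag(g@ttWeights@values)
  dt <- g@dtEdges@values
  out <- switch(structure,
    C1 = dd %*% dt,
    C2 = dt %*% tt,
    C3 = .zeroDiag(dd %*% dd) %*% dt,
    C4 = dt %*% .zeroDiag(tt %*% tt),
    C5 = dd %*% dt %*% tt,
    C6 = dt %*% crossprod(dt) - rowSums(dt^2) * dt -
      sweep(dt, 2, colSums(dt^2), `*`) + dt^3)
  dimnames(out) <- dimnames(dt)
  # guard against negative round-off from the corrections
  out[out < 0] <- 0
  out
}

#' Max meta-path score matrix
#'
#' For every (drug, target) pair, the largest edge-weight product over all
#' simple paths of the given structure (0 when none exists), computed by
#' max-times matrix composition over the same chains as
#' \code{\link{sumScoreMatrix}}; intermediate diagonals are zeroed to mask
#' non-simple walks. For C6 every drug-target edge has weight exactly 1, so
#' every simple path has product 1 and the Max score is the indicator that
#' at least one simple path exists.
#'
#' @inheritParams sumScoreMatrix
#' @return numeric drugs x targets matrix of Max scores
#' @export
maxScoreMatrix <- function(g, structure) {
  structure <- match.arg(structure, pathStructures)
  dd <- .zeroDiag(g@ddWeights@values)
  tt <- .zeroDiag(g@ttWeights@values)
  dt <- g@dtEdges@values
  out <- switch(structure,
    C1 = .maxTimes(dd, dt),
    C2 = .maxTimes(dt, tt),
    C3 = .maxTimes(.zeroDiag(.maxTimes(dd, dd)), dt),
    C4 = .maxTimes(dt, .zeroDiag(.maxTimes(tt, tt))),
    C5 = .maxTimes(.maxTimes(dd, dt), tt),
    C6 = (sumScoreMatrix(g, "C6") > 1e-12) * 1)
  dimnames(out) <- dimnames(dt)
  out
}

#' Raw 12-column path-feature matrix of one graph
#'
#' One row per (drug, target) pair (drug index varying fastest, matching
#' \code{as.vector} on drugs x targets matrices), one column per
#' {structure} x {Sum, Max} combination, named \code{"<structure>_<kind>"}.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @return numeric (nDrugs * nTargets) x 12 matrix
#' @export
pathFeatureMatrix <- function(g) {
  cols <- lapply(pathStructures, function(s)
    cbind(as.vector(sumScoreMatrix(g, s)), as.vector(maxScoreMatrix(g, s))))
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(pathStructures, function(s)
    paste0(s, c("_Sum", "_Max")), character(2)))
  out
}

#' Fit / apply per-column min-max normalization
#'
#' \code{fitMinMax} records each column's minimum and maximum over the rows
#' it is given (the training pairs, to keep test information out of the
#' fit); \code{applyMinMax} rescales columns to [0, 1] with that fit,
#' clipping values outside the fitted range. Constant columns map to 0.
#'
#' @param x numeric matrix
#' @return \code{fitMinMax}: list with \code{min}, \code{max} per column
#' @export
fitMinMax <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname fitMinMax
#' @param fit a fit from \code{fitMinMax}
#' @return \code{applyMinMax}: the rescaled matrix
#' @export
applyMinMax <- function(x, fit) {
  rng <- fit$max - fit$min
  out <- sweep(x, 2, fit$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], `/`)
  out[, !nz] <- 0
  pmin(pmax(out, 0), 1)
}

#' Extract the 24-dimensional pair feature vectors
#'
#' Concatenates the {Sum, Max} x {C1..C6} path scores of the two
#' heterogeneous graphs (fused-similarity G1 and embedding-cosine G2) into
#' one 24-column feature matrix over all drug-target pairs, min-max
#' normalized per column, with labels taken from \code{labelSource}
#' (default: the drug-target edges of \code{g1}). Scores from different
#' path structures are never mixed in one feature.
#'
#' @param g1,g2 \linkS4class{HeteroGraph}s over the same identifier spaces
#' @param labelSource optional \linkS4class{InteractionMatrix} supplying the
#'   0/1 labels (use the unmasked interactions during cross-validation)
#' @param normalize min-max normalize columns over all pairs (default TRUE;
#'   cross-validation instead fits on training rows only via
#'   \code{\link{fitMinMax}})
#' @return a \linkS4class{PairDataset} with 24 features per pair
#' @export
extractPairFeatures <- function(g1, g2, labelSource = NULL, normalize = TRUE) {
  if (!identical(drugNames(g1), drugNames(g2)) ||
      !identical(targetNames(g1), targetNames(g2)))
    stop("g1 and g2 do not share identifier spaces")
  f1 <- pathFeatureMatrix(g1)
  f2 <- pathFeatureMatrix(g2)
  colnames(f1) <- paste0("G1_", colnames(f1))
  colnames(f2) <- paste0("G2_", colnames(f2))
  feats <- cbind(f1, f2)
  if (normalize) feats <- applyMinMax(feats, fitMinMax(feats))
  if (is.null(labelSource)) labelSource <- g1@dtEdges
  pairs <- expand.grid(drug = drugNames(g1), target = targetNames(g1),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  PairDataset(pairs, feats, as.integer(as.vector(labelSource@values)))
}

#' Drop or greedily select pair features
#'
#' By default drops the four D-T-D-T (C6) Sum/Max features of both graphs,
#' which are built from the sparse known-interaction edges alone and carry
#' little signal, leaving 20 features. Optional greedy forward selection
#' over the remaining features (using a caller-supplied evaluator mapping a
#' feature-name subset to a validation score) can reduce the set further.
#'
#' @param ds a \linkS4class{PairDataset}
#' @param drop feature names to remove; default all \code{*_C6_*} columns
#' @param forwardSelection run greedy forward selection after dropping
#' @param evaluator function(featureNames) -> scalar score; required when
#'   \code{forwardSelection} is TRUE
#' @param epsilon minimum gain to keep adding features, default 1e-4
#' @return a \linkS4class{PairDataset} with the reduced feature set
#' @export
selectFeatures <- function(ds, drop = grep("_C6_", colnames(ds@features),
                                           value = TRUE),
                           forwardSelection = FALSE, evaluator = NULL,
                           epsilon = 1e-4) {
  nms <- colnames(ds@features)
  unknown <- setdiff(drop, nms)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(nms, drop)
  if (forwardSelection) {
    if (is.null(evaluator)) stop("forward selection requires an evaluator")
    sel <- character(0)
    best <- -Inf
    repeat {
      remain <- setdiff(keep, sel)
      if (!length(remain)) break
      scores <- vapply(remain, function(f) evaluator(c(sel, f)), numeric(1))
      ord <- order(-scores, remain)
      if (scores[ord[1]] - best <= epsilon) break
      sel <- c(sel, remain[ord[1]])
      best <- scores[ord[1]]
    }
    keep <- sel
  }
  PairDataset(ds@pairs, ds@features[, keep, drop = FALSE], ds@labels)
}
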