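# Shared fixture builders; everything is generated in code.

simMat <- function(v, ids, diagonal = "zero") {
  SimilarityMatrix(v, ids = ids, diagonal = diagonal)
}

# random heterogeneous graph with symmetric similarity weights and a binary
# interaction layer
randomHeteroGraph <- function(nDrugs, nTargets, pEdge = 0.4, pSim = 0.7,
                              seed = 1) {
  set.seed(seed)
  dIds <- paste0("d", seq_len(nDrugs))
  tIds <- paste0("t", seq_len(nTargets))
  rsym <- function(n) {
    v <- matrix(stats::runif(n * n), n, n) *
      matrix(stats::rbinom(n * n, 1, pSim), n, n)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    v
  }
  dt <- matrix(stats::rbinom(nDrugs * nTargets, 1, pEdge), nDrugs, nTargets,
               dimnames = list(dIds, tIds))
  buildHeteroGraph(simMat(rsym(nDrugs), dIds), simMat(rsym(nTargets), tIds),
                   InteractionMatrix(dt))
}

# toy graph shared by several modules: 2 drugs, 3 targets, five nodes total
fiveNodeGraph <- function() {
  dd <- matrix(c(0, .6, .6, 0), 2, 2)
  tt <- matrix(c(0, .5, .2, .5, 0, .9, .2, .9, 0), 3, 3)
  dt <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3,
               dimnames = list(c("d1", "d2"), c("t1", "t2", "t3")))
  buildHeteroGraph(simMat(dd, c("d1", "d2")), simMat(tt, c("t1", "t2", "t3")),
                   InteractionMatrix(dt))
}

# interaction matrix with the shape and density of the smallest benchmark
# dataset (54 drugs x 26 targets, 90 known DTIs)
nrShapedInteraction <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(0, 54, 26,
              dimnames = list(sprintf("D%02d", 1:54), sprintf("T%02d", 1:26)))
  m[sample(length(m), 90)] <- 1
  InteractionMatrix(m)
}

# small planted benchmark for pipeline-level tests
smallBundle <- function(seed = 5, ...) {
  makeSyntheticBenchmark(synthConfig(nDrugs = 20, nTargets = 14,
                                     nClusters = 2, seed = seed, ...))
}

# brute-force AUC: average over all positive-negative score comparisons
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# worst deviation between the matrix-product scores and the enumeration
# oracle over all structures and all pairs of one graph
oracleDiscrepancy <- function(g) {
  worst <- 0
  for (s in pathStructures) {
    sm <- sumScoreMatrix(g, s)
    mm <- maxScoreMatrix(g, s)
    for (d in drugNames(g)) for (t in targetNames(g)) {
      o <- enumerateSimplePathScores(g, d, t, s)
      worst <- max(worst,
                   abs(sm[d, t] - sum(o)),
                   abs(mm[d, t] - (if (length(o)) max(o) else 0)))
    }
  }
  worst
}

expectScoresMatchOracle <- function(g, tol = 1e-9) {
  expect_lt(oracleDiscrepancy(g), tol)
}
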