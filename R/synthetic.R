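#' Synthetic benchmark configuration
#'
#' Parameters of the planted-cluster generator. Drugs and targets are
#' assigned to paired clusters; informative similarity views draw
#' within-cluster similarities from the high truncated-Gaussian
#' distribution and between-cluster ones from the low distribution, noise
#' views are cluster-independent, and interactions are Bernoulli with a
#' high probability for matched-cluster pairs and a low one otherwise --
#' the "guilt-by-association" structure the prediction method exploits.
#' The defaults give a realized sparsity ratio around 0.09, in the range of
#' the small gold-standard benchmarks.
#'
#' @param nDrugs,nTargets entity counts, defaults 60 and 40
#' @param nClusters number of paired clusters, default 4
#' @param intraMean,intraSd within-cluster similarity distribution
#'   (default 0.8, 0.05)
#' @param interMean,interSd between-cluster similarity distribution
#'   (default 0.2, 0.05)
#' @param pMatched,pUnmatched interaction probabilities for matched /
#'   unmatched cluster pairs (defaults 0.3, 0.01)
#' @param nInformativeViews,nNoiseViews similarity views per side,
#'   defaults 2 and 1
#' @param seed integer seed, default 42
#' @return a \code{synthConfig} list
#' @export
synthConfig <- function(nDrugs = 60, nTargets = 40, nClusters = 4,
                        intraMean = 0.8, intraSd = 0.05,
                        interMean = 0.2, interSd = 0.05,
                        pMatched = 0.3, pUnmatched = 0.01,
                        nInformativeViews = 2, nNoiseViews = 1, seed = 42) {
  cfg <- list(nDrugs = nDrugs, nTargets = nTargets, nClusters = nClusters,
              intraMean = intraMean, intraSd = intraSd,
              interMean = interMean, interSd = interSd,
              pMatched = pMatched, pUnmatched = pUnmatched,
              nInformativeViews = nInformativeViews,
              nNoiseViews = nNoiseViews, seed = as.integer(seed))
  if (nClusters > min(nDrugs, nTargets))
    stop("more clusters than entities on one side")
  if (intraMean <= interMean)
    stop("within-cluster similarity mean must exceed the between-cluster mean")
  if (pMatched <= pUnmatched)
    stop("matched interaction probability must exceed the unmatched one")
  structure(cfg, class = "synthConfig")
}

.truncGaussSim <- function(n, means, sd) {
  # symmetric matrix with unit diagonal; entrywise truncated Gaussian
  v <- matrix(0, n, n)
  up <- upper.tri(v)
  v[up] <- pmin(pmax(stats::rnorm(sum(up), means[up], sd), 0), 1)
  v <- v + t(v)
  diag(v) <- 1
  v
}

#' Generate a planted-cluster benchmark bundle
#'
#' See \code{\link{synthConfig}} for the generative model. Reproducible
#' under the config seed; every generated informative view is asserted to
#' place higher mean similarity within clusters than between them.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return a \linkS4class{DatasetBundle} with views named
#'   \code{informative_<i>} / \code{noise_<i>} per side
#' @examples
#' bundle <- makeSyntheticBenchmark(synthConfig(nDrugs = 20, nTargets = 15))
#' datasetStatistics(bundle)
#' @export
makeSyntheticBenchmark <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  dIds <- sprintf("d%03d", seq_len(cfg$nDrugs))
  tIds <- sprintf("t%03d", seq_len(cfg$nTargets))
  dClust <- rep(seq_len(cfg$nClusters), length.out = cfg$nDrugs)
  tClust <- rep(seq_len(cfg$nClusters), length.out = cfg$nTargets)

  makeViews <- function(clust, ids, side) {
    n <- length(ids)
    sameClust <- outer(clust, clust, `==`)
    views <- list()
    for (i in seq_len(cfg$nInformativeViews)) {
      means <- ifelse(sameClust, cfg$intraMean, cfg$interMean)
      v <- .truncGaussSim(n, means, ifelse(sameClust, cfg$intraSd,
                                           cfg$interSd))
      off <- row(v) != col(v)
      stopifnot(mean(v[sameClust & off]) > mean(v[!sameClust]))
      views[[paste0("informative_", i)]] <-
        SimilarityMatrix(v, ids = ids, diagonal = "unit")
    }
    for (i in seq_len(cfg$nNoiseViews)) {
      means <- matrix((cfg$intraMean + cfg$interMean) / 2, n, n)
      v <- .truncGaussSim(n, means, cfg$intraSd + cfg$interSd)
      views[[paste0("noise_", i)]] <-
        SimilarityMatrix(v, ids = ids, diagonal = "unit")
    }
    views
  }
  drugSims <- makeViews(dClust, dIds, "drug")
  targetSims <- makeViews(tClust, tIds, "target")

  matched <- outer(dClust, tClust, `==`)
  prob <- ifelse(matched, cfg$pMatched, cfg$pUnmatched)
  dti <- matrix(stats::rbinom(length(prob), 1, prob), cfg$nDrugs,
                cfg$nTargets, dimnames = list(dIds, tIds))
  DatasetBundle(InteractionMatrix(dti), drugSims, targetSims)
}

#' The fixed two-drug / two-target worked example
#'
#' A minimal bundle whose graph has three edges: DD(d1, d2) = 0.5,
#' TT(t1, t2) = 0.4 and the interaction d2-t1. Its path scores are small
#' enough to verify by hand (e.g. the D-D-T Sum score of (d1, t1) is 0.5
#' and the D-T-T Sum score of (d2, t2) is 0.4; no three-drug path exists).
#'
#' @return a \linkS4class{DatasetBundle} with one similarity view per side
#' @export
makeWorkedToy <- function() {
  dd <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  tt <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  dti <- matrix(c(0, 1, 0, 0), 2, 2,
                dimnames = list(c("d1", "d2"), c("t1", "t2")))
  DatasetBundle(
    InteractionMatrix(dti),
    drugSims = list(main = SimilarityMatrix(dd, ids = c("d1", "d2"),
                                            diagonal = "unit")),
    targetSims = list(main = SimilarityMatrix(tt, ids = c("t1", "t2"),
                                              diagonal = "unit")))
}
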