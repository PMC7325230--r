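#' Gaussian interaction profile (GIP) kernel
#'
#' Treats each drug's row (or each target's column) of the interaction
#' matrix as its interaction profile y and computes
#' K(a, b) = exp(-gamma * ||y_a - y_b||^2) with the bandwidth
#' gamma = gammaScale / mean(||y_a||^2). The bandwidth scaler defaults to 1,
#' the convention of the kernel's original formulation.
#'
#' @param interactions an \linkS4class{InteractionMatrix}
#' @param axis \code{"drugs"} (profiles are rows) or \code{"targets"}
#'   (profiles are columns)
#' @param gammaScale bandwidth scaler, default 1
#' @return a unit-diagonal \linkS4class{SimilarityMatrix}
#' @examples
#' toy <- makeWorkedToy()
#' gipKernel(toy@interactions, "drugs")
#' @export
gipKernel <- function(interactions, axis = c("drugs", "targets"),
                      gammaScale = 1) {
  axis <- match.arg(axis)
  y <- interactions@values
  if (axis == "targets") y <- t(y)
  norms <- rowSums(y^2)
  if (all(norms == 0))
    stop("GIP bandwidth undefined: interaction matrix has no known DTIs")
  gamma <- gammaScale / mean(norms)
  # squared distances via the Gram expansion
  g <- tcrossprod(y)
  d2 <- outer(norms, norms, "+") - 2 * g
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  SimilarityMatrix(k, ids = rownames(y), diagonal = "unit")
}

#' Integrate multiple similarity views
#'
#' Combines similarity views sharing one entity namespace by the elementwise
#' average (AVG), geometric mean (GeoM) or maximum (MAX), or by similarity
#' network fusion (SNF, see \code{\link{snfFuse}}).
#'
#' @param views list of \linkS4class{SimilarityMatrix} over the same entities
#' @param method \code{"SNF"}, \code{"AVG"}, \code{"GeoM"} or \code{"MAX"}
#' @param snfK,snfT SNF neighbourhood size and iteration count, passed to
#'   \code{\link{snfFuse}}
#' @return a \linkS4class{SimilarityMatrix} with the views' diagonal
#'   convention
#' @export
integrateSimilarities <- function(views,
                                  method = c("SNF", "AVG", "GeoM", "MAX"),
                                  snfK = NULL, snfT = 20) {
  method <- match.arg(method)
  stopifnot(length(views) >= 1)
  ids <- entityNames(views[[1]])
  diagc <- simDiagonal(views[[1]])
  for (v in views) {
    if (!identical(entityNames(v), ids))
      stop("similarity views do not share entity identifiers")
    if (simDiagonal(v) != diagc)
      stop("similarity views mix diagonal conventions")
  }
  if (method == "SNF") return(snfFuse(views, K = snfK, t = snfT))
  arrs <- lapply(views, function(v) v@values)
  out <- switch(method,
    AVG = Reduce(`+`, arrs) / length(arrs),
    MAX = Reduce(pmax, arrs),
    GeoM = {
      logs <- Reduce(`+`, lapply(arrs, function(a) log(pmax(a, 0))))
      exp(logs / length(arrs))   # 0 whenever any view is 0
    })
  SimilarityMatrix(out, ids = ids, diagonal = diagc)
}

#' Similarity network fusion (SNF)
#'
#' Nonlinear cross-diffusion that merges several similarity networks into
#' one. Each view v is turned into a row-stochastic full kernel P_v (with
#' the half-mass diagonal convention) and a KNN-restricted local kernel S_v;
#' the update P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v) is iterated t
#' times with symmetrization and renormalization. The final average of the
#' P_v is rescaled so its largest off-diagonal entry is 1, and the diagonal
#' is set per the views' convention. A single view is returned unchanged.
#'
#' @param views list of \linkS4class{SimilarityMatrix} over the same entities
#' @param K neighbourhood size; default \code{min(20, k - 1)} for k entities
#' @param t number of diffusion iterations, default 20
#' @return a fused \linkS4class{SimilarityMatrix}
#' @export
snfFuse <- function(views, K = NULL, t = 20) {
  stopifnot(length(views) >= 1, t >= 1)
  ids <- entityNames(views[[1]])
  diagc <- simDiagonal(views[[1]])
  k <- length(ids)
  if (k < 2) stop("SNF needs at least two entities")
  if (length(views) == 1) return(views[[1]])
  if (is.null(K)) K <- min(20, k - 1)
  if (K < 1 || K >= k) stop("SNF neighbourhood size K must be in [1, k - 1]")

  normFull <- function(w) {
    # row-stochastic with half the mass on the diagonal
    diag(w) <- 0
    rs <- rowSums(w)
    p <- w / (2 * pmax(rs, .Machine$double.eps))
    p[rs == 0, ] <- 0
    diag(p) <- 1 / 2
    p
  }
  normLocal <- function(w) {
    diag(w) <- 0
    s <- matrix(0, k, k)
    for (i in seq_len(k)) {
      nb <- order(w[i, ], decreasing = TRUE)[seq_len(K)]
      tot <- sum(w[i, nb])
      if (tot > 0) s[i, nb] <- w[i, nb] / tot
    }
    s
  }

  W <- lapply(views, function(v) v@values)
  P <- lapply(W, normFull)
  S <- lapply(W, normLocal)
  nv <- length(W)
  for (iter in seq_len(t)) {
    Pnew <- vector("list", nv)
    for (v in seq_len(nv)) {
      others <- Reduce(`+`, P[-v]) / (nv - 1)
      q <- S[[v]] %*% others %*% t(S[[v]])
      q <- (q + t(q)) / 2
      Pnew[[v]] <- normFull(q)
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / nv
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 0
  mx <- max(fused)
  if (mx > 0) fused <- fused / mx
  SimilarityMatrix(fused, ids = ids, diagonal = diagc)
}

#' Forward similarity selection (FSS)
#'
#' Greedy selection of informative similarity views. Round 1 scans every
#' (drug view, target view) pair and fixes the best-scoring pair; each later
#' round tries adding one more drug view and one more target view (their
#' SNF-fused combinations are what the evaluator scores) and accepts the
#' best candidate while it improves the score by more than \code{epsilon}.
#' Ties are broken by lexicographic view name for reproducibility.
#'
#' @param drugViews,targetViews named lists of \linkS4class{SimilarityMatrix}
#' @param evaluator function(drugViewNames, targetViewNames) returning a
#'   scalar validation AUPR; see \code{\link{makeLinkEvaluator}}
#' @param epsilon minimum score gain to continue, default 1e-4
#' @param independentSides when TRUE a side whose candidates are exhausted
#'   stops growing while the other continues; when FALSE (default) rounds
#'   add one view to both sides and stop when either side is exhausted
#' @return a \linkS4class{SelectionResult}
#' @export
forwardSimilaritySelection <- function(drugViews, targetViews, evaluator,
                                       epsilon = 1e-4,
                                       independentSides = FALSE) {
  stopifnot(length(drugViews) >= 1, length(targetViews) >= 1,
            !is.null(names(drugViews)), !is.null(names(targetViews)))
  evalSafe <- function(dd, tt, round) {
    sc <- tryCatch(evaluator(dd, tt), error = function(e)
      stop(sprintf("FSS evaluator failed in round %d for [%s] x [%s]: %s",
                   round, paste(dd, collapse = ","),
                   paste(tt, collapse = ","), conditionMessage(e))))
    as.numeric(sc)
  }
  scoreBoard <- function(cand, round) {
    cand$score <- vapply(seq_len(nrow(cand)), function(i)
      evalSafe(cand$dd[[i]], cand$tt[[i]], round), numeric(1))
    cand[order(-cand$score, cand$label), , drop = FALSE]
  }

  # round 1: all single pairs
  grid <- expand.grid(d = sort(names(drugViews)), t = sort(names(targetViews)),
                      stringsAsFactors = FALSE)
  cand <- data.frame(label = paste(grid$d, grid$t, sep = " | "),
                     stringsAsFactors = FALSE)
  cand$dd <- as.list(grid$d)
  cand$tt <- as.list(grid$t)
  cand <- scoreBoard(cand, 1L)
  selD <- cand$dd[[1]]; selT <- cand$tt[[1]]
  best <- cand$score[1]
  trace <- list(data.frame(candidate = cand$label, score = cand$score))
  accepted <- best

  round <- 1L
  repeat {
    round <- round + 1L
    remD <- sort(setdiff(names(drugViews), selD))
    remT <- sort(setdiff(names(targetViews), selT))
    if (independentSides) {
      if (!length(remD) && !length(remT)) break
      if (!length(remD)) remD <- NA_character_
      if (!length(remT)) remT <- NA_character_
    } else if (!length(remD) || !length(remT)) break
    grid <- expand.grid(d = remD, t = remT, stringsAsFactors = FALSE)
    cand <- data.frame(label = paste(ifelse(is.na(grid$d), "-", grid$d),
                                     ifelse(is.na(grid$t), "-", grid$t),
                                     sep = " | "), stringsAsFactors = FALSE)
    cand$dd <- lapply(grid$d, function(d) c(selD, d[!is.na(d)]))
    cand$tt <- lapply(grid$t, function(t) c(selT, t[!is.na(t)]))
    cand <- scoreBoard(cand, round)
    trace[[round]] <- data.frame(candidate = cand$label, score = cand$score)
    if (cand$score[1] - best <= epsilon) break
    selD <- cand$dd[[1]]; selT <- cand$tt[[1]]
    best <- cand$score[1]
    accepted <- c(accepted, best)
  }
  new("SelectionResult", selectedDrugViews = selD, selectedTargetViews = selT,
      trace = trace, scores = accepted)
}

#' Default FSS evaluator: meta-path scoring on an inner validation split
#'
#' Builds a light-weight evaluator for \code{\link{forwardSimilaritySelection}}
#' that avoids a full cross-validation per candidate. A fixed fraction of
#' the known interactions is held out (deterministically under \code{seed});
#' a candidate view subset is fused per side (SNF when more than one view),
#' the held-out edges are masked, every pair is scored by the sum of the
#' D-D-T, D-T-T and D-D-T-T meta-path Sum scores on the resulting graph, and
#' the AUPR of recovering the held-out positives among all non-training
#' pairs is returned.
#'
#' @param bundle a \linkS4class{DatasetBundle}
#' @param holdout fraction of known DTIs held out for validation, default 0.2
#' @param seed integer seed for the holdout split
#' @param snfK,snfT SNF parameters used when fusing multi-view candidates
#' @return function(drugViewNames, targetViewNames) -> AUPR
#' @export
makeLinkEvaluator <- function(bundle, holdout = 0.2, seed = 1,
                              snfK = NULL, snfT = 20) {
  dti <- bundle@interactions@values
  pos <- which(dti == 1)
  if (length(pos) < 2) stop("evaluator needs at least two known DTIs")
  nHold <- max(1L, round(holdout * length(pos)))
  set.seed(seed)
  held <- sample(pos, nHold)
  dtTrain <- dti
  dtTrain[held] <- 0
  labels <- as.integer(seq_along(dti) %in% held)
  candidateIdx <- which(dtTrain == 0)   # exclude training positives
  function(drugViewNames, targetViewNames) {
    dd <- integrateSimilarities(bundle@drugSims[drugViewNames],
                                method = "SNF", snfK = snfK, snfT = snfT)
    tt <- integrateSimilarities(bundle@targetSims[targetViewNames],
                                method = "SNF", snfK = snfK, snfT = snfT)
    g <- buildHeteroGraph(dd, tt, InteractionMatrix(
      dtTrain, rownames(dti), colnames(dti)))
    sc <- sumScoreMatrix(g, "C1") + sumScoreMatrix(g, "C2") +
      sumScoreMatrix(g, "C5")
    computeAUPR(as.vector(sc)[candidateIdx], labels[candidateIdx])
  }
}
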