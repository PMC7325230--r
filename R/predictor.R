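# Deterministic fan-out of one top-level seed to per-stage, per-fold seeds.
.STAGE_IDS <- c(folds = 1L, walks = 2L, sampler = 3L, classifier = 4L,
                evaluator = 5L, synth = 6L)
.childSeed <- function(seed, stage, k = 0L) {
  sid <- .STAGE_IDS[[stage]]
  as.integer((as.double(seed) * 131 + sid * 1009 + k * 17) %% 2147483647)
}

#' Sampler configuration
#'
#' @param method \code{"random"} (random oversampling with replacement) or
#'   \code{"smote"} (synthetic minority interpolation)
#' @param smoteNeighbors number of minority nearest neighbours SMOTE
#'   interpolates towards; must be below the minority count
#' @param seed integer seed
#' @return a \code{samplerConfig} list
#' @export
samplerConfig <- function(method = c("random", "smote"), smoteNeighbors = 5,
                          seed = 1) {
  structure(list(method = match.arg(method),
                 smoteNeighbors = as.integer(smoteNeighbors),
                 seed = as.integer(seed)), class = "samplerConfig")
}

#' Classifier configuration
#'
#' \code{"auto"} picks a multilayer perceptron for very small datasets
#' (fewer than 2000 pairs, where high-variance data favours it) and
#' AdaBoost otherwise. Hyperparameters: \code{hidden}, \code{decay},
#' \code{maxit} for the NN; \code{nTrees} for the random forest;
#' \code{nEstimators} and \code{maxDepth} (base-tree depth) for AdaBoost.
#'
#' @param kind one of \code{"auto"}, \code{"NN"}, \code{"RF"},
#'   \code{"AdaBoost"}; the diagnostic kinds \code{"oracle"} (emits the true
#'   test labels) and \code{"constant"} (emits 0.5 everywhere) exist to
#'   calibrate the evaluation machinery and are only meaningful inside
#'   \code{\link{runCrossValidation}}
#' @param hidden,decay,maxit NN hyperparameters
#' @param nTrees RF tree count
#' @param nEstimators,maxDepth AdaBoost rounds and base-tree depth
#' @param seed integer seed
#' @return a \code{classifierConfig} list
#' @export
classifierConfig <- function(kind = c("auto", "NN", "RF", "AdaBoost",
                                      "oracle", "constant"),
                             hidden = 16, decay = 1e-3, maxit = 200,
                             nTrees = 300, nEstimators = 50, maxDepth = 2,
                             seed = 1) {
  structure(list(kind = match.arg(kind), hidden = hidden, decay = decay,
                 maxit = maxit, nTrees = nTrees, nEstimators = nEstimators,
                 maxDepth = maxDepth, seed = as.integer(seed)),
            class = "classifierConfig")
}

#' Enumerate all drug-target pairs with labels
#'
#' Builds the label-only pair skeleton: every (drug, target) pair, labelled
#' 1 when the interaction is known and 0 otherwise; the negative set is
#' exactly the complement of the positives (no sampling).
#'
#' @param dti an \linkS4class{InteractionMatrix}
#' @return a \linkS4class{PairDataset} with zero feature columns
#' @export
buildPairDataset <- function(dti) {
  pairs <- expand.grid(drug = drugNames(dti), target = targetNames(dti),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  PairDataset(pairs, labels = as.integer(as.vector(dti@values)))
}

#' Stratified fold assignment
#'
#' Randomly partitions indices into \code{nFolds} groups, stratified by
#' label: within each class, shuffled members are dealt round-robin, so
#' per-fold class counts differ by at most one.
#'
#' @param labels 0/1 vector
#' @param nFolds number of folds, default 10
#' @param seed integer seed
#' @return integer vector of fold ids (1..nFolds), one per index
#' @export
makeFoldPlan <- function(labels, nFolds = 10, seed = 1) {
  stopifnot(nFolds >= 2)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
  }
  fold
}

#' Oversample the minority class
#'
#' Equalizes class counts on training data. Random oversampling duplicates
#' existing minority rows (sampled with replacement); SMOTE adds convex
#' combinations of a minority row and one of its \code{smoteNeighbors}
#' nearest minority neighbours (Euclidean distance in feature space).
#'
#' @param features numeric matrix of training features
#' @param labels 0/1 training labels, both classes present
#' @param cfg a \code{\link{samplerConfig}}
#' @return list with balanced \code{features} and \code{labels}
#' @export
oversamplePairs <- function(features, labels, cfg = samplerConfig()) {
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0)) stop("oversampling needs both classes present")
  minor <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  need <- abs(counts[["0"]] - counts[["1"]])
  if (need == 0) return(list(features = features, labels = labels))
  minIdx <- which(labels == minor)
  set.seed(cfg$seed)
  if (cfg$method == "random") {
    extra <- features[sample(minIdx, need, replace = TRUE), , drop = FALSE]
  } else {
    k <- cfg$smoteNeighbors
    if (k >= length(minIdx))
      stop("smoteNeighbors must be below the minority count")
    xm <- features[minIdx, , drop = FALSE]
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nbr <- matrix(0L, nrow(xm), k)
    for (i in seq_len(nrow(xm))) nbr[i, ] <- order(d[i, ])[seq_len(k)]
    base <- sample.int(nrow(xm), need, replace = TRUE)
    mate <- nbr[cbind(base, sample.int(k, need, replace = TRUE))]
    u <- stats::runif(need)
    extra <- xm[base, , drop = FALSE] +
      u * (xm[mate, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  list(features = rbind(features, extra),
       labels = c(labels, rep(minor, need)))
}

.resolveKind <- function(cfg, nPairs) {
  if (cfg$kind != "auto") return(cfg$kind)
  if (nPairs < 2000) "NN" else "AdaBoost"
}

.fitAdaBoost <- function(x, y, nEstimators, maxDepth, seed) {
  set.seed(seed)
  df <- data.frame(y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxDepth, cp = 0, xval = 0,
                               minsplit = 10)
  for (m in seq_len(nEstimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    miss <- pred != df$y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5 && length(trees)) break
    err <- min(max(err, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    if (sum(miss) == 0) break
  }
  list(trees = trees, alphas = alphas)
}

.predictAdaBoost <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- rep(0, nrow(df))
  for (m in seq_along(model$trees)) {
    h <- ifelse(predict(model$trees[[m]], df, type = "class") == "1", 1, -1)
    f <- f + model$alphas[m] * h
  }
  (f / sum(model$alphas) + 1) / 2
}

#' Fit a DTI classifier
#'
#' Trains the configured classifier on a feature matrix: a single-hidden-
#' layer perceptron (\pkg{nnet}), a random forest (\pkg{randomForest}), or
#' discrete AdaBoost over \pkg{rpart} decision trees. Deterministic under
#' the configuration seed.
#'
#' @param x numeric feature matrix
#' @param y 0/1 labels
#' @param cfg a \code{\link{classifierConfig}}
#' @return a fitted model for \code{\link{predictScores}}
#' @export
fitClassifier <- function(x, y, cfg = classifierConfig()) {
  kind <- .resolveKind(cfg, nrow(x))
  fit <- switch(kind,
    NN = {
      set.seed(cfg$seed)
      nnet::nnet(x = x, y = as.numeric(y), size = cfg$hidden,
                 decay = cfg$decay, maxit = cfg$maxit, entropy = TRUE,
                 trace = FALSE, MaxNWts = 1e5)
    },
    RF = {
      set.seed(cfg$seed)
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = cfg$nTrees)
    },
    AdaBoost = .fitAdaBoost(x, y, cfg$nEstimators, cfg$maxDepth, cfg$seed))
  structure(list(kind = kind, fit = fit), class = "dtiClassifier")
}

#' Score pairs with a fitted classifier
#'
#' @param model a model from \code{\link{fitClassifier}}
#' @param x numeric feature matrix
#' @return numeric scores in [0, 1], higher = more likely interacting
#' @export
predictScores <- function(model, x) {
  switch(model$kind,
    NN = as.numeric(predict(model$fit, x)),
    RF = as.numeric(predict(model$fit, x, type = "prob")[, "1"]),
    AdaBoost = .predictAdaBoost(model$fit, x))
}

#' Fit all train-side artifacts of one cross-validation fold
#'
#' Fits the min-max normalizer, the oversampler and the classifier strictly
#' on the training rows; nothing about the held-out rows enters any fit.
#' Exposed separately so leak-freedom can be asserted directly: perturbing
#' test rows must leave every returned artifact identical.
#'
#' @param features raw (unnormalized) feature matrix over all pairs
#' @param labels 0/1 labels over all pairs
#' @param trainIdx integer indices of the training pairs
#' @param sampler a \code{\link{samplerConfig}}
#' @param classifier a \code{\link{classifierConfig}}
#' @return list with \code{normalizer}, \code{sampled} (balanced training
#'   set) and \code{model}
#' @export
fitFoldModel <- function(features, labels, trainIdx,
                         sampler = samplerConfig(),
                         classifier = classifierConfig()) {
  normalizer <- fitMinMax(features[trainIdx, , drop = FALSE])
  xtr <- applyMinMax(features[trainIdx, , drop = FALSE], normalizer)
  sampled <- oversamplePairs(xtr, labels[trainIdx], sampler)
  model <- fitClassifier(sampled$features, sampled$labels, classifier)
  list(normalizer = normalizer, sampled = sampled, model = model)
}

# Features for one fold: mask test positives, rebuild G/G1/G2, extract the
# 24 raw path-score columns and drop the configured ones.
.foldFeatures <- function(bundle, fusedDD, fusedTT, maskPairs, config, fold) {
  dtTrain <- maskTestEdges(
    buildHeteroGraph(fusedDD, fusedTT, bundle@interactions), maskPairs)@dtEdges
  kEff <- min(config$knnK, length(drugNames(bundle)) - 1,
              length(targetNames(bundle)) - 1)
  gEmbed <- buildHeteroGraph(knnSparsify(fusedDD, kEff),
                             knnSparsify(fusedTT, kEff), dtTrain)
  wcfg <- config$walk
  wcfg$seed <- .childSeed(config$seed, "walks", fold)
  embRes <- embedGraph(gEmbed, wcfg)
  g1 <- buildHeteroGraph(fusedDD, fusedTT, dtTrain)
  g2 <- buildHeteroGraph(embRes$Md, embRes$Mt, dtTrain)
  f1 <- pathFeatureMatrix(g1); colnames(f1) <- paste0("G1_", colnames(f1))
  f2 <- pathFeatureMatrix(g2); colnames(f2) <- paste0("G2_", colnames(f2))
  feats <- cbind(f1, f2)
  if (length(config$dropFeatures))
    feats <- feats[, setdiff(colnames(feats), config$dropFeatures),
                   drop = FALSE]
  feats
}

.fuseBundle <- function(bundle, config) {
  list(dd = integrateSimilarities(bundle@drugSims,
                                  method = config$fusionMethod,
                                  snfK = config$snfK, snfT = config$snfT),
       tt = integrateSimilarities(bundle@targetSims,
                                  method = config$fusionMethod,
                                  snfK = config$snfK, snfT = config$snfT))
}

#' Stratified cross-validation of the full prediction pipeline
#'
#' For each fold: the test-fold known interactions are masked from every
#' graph, the embedding-input graph G (KNN-sparsified fused similarities
#' plus training interactions) is re-embedded, the fused graph G1 and the
#' cosine graph G2 are rebuilt, path-score features are extracted, and the
#' normalizer, oversampler and classifier are fitted on training pairs only
#' before scoring the test pairs. Per-fold and mean AUPR/AUC (and mean
#' average precision over drugs) are reported.
#'
#' @param bundle a \linkS4class{DatasetBundle} with at least one similarity
#'   view per side
#' @param config a \code{\link{runConfig}}
#' @return a \linkS4class{MetricsReport}
#' @export
runCrossValidation <- function(bundle, config = runConfig()) {
  dti <- bundle@interactions
  labels <- as.integer(as.vector(dti@values))
  pairs <- buildPairDataset(dti)@pairs
  folds <- makeFoldPlan(labels, config$nFolds, .childSeed(config$seed, "folds"))
  fused <- .fuseBundle(bundle, config)
  rows <- vector("list", config$nFolds)
  for (f in seq_len(config$nFolds)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    maskPairs <- pairs[testIdx[labels[testIdx] == 1], , drop = FALSE]
    feats <- .foldFeatures(bundle, fused$dd, fused$tt, maskPairs, config, f)
    scfg <- config$sampler; scfg$seed <- .childSeed(config$seed, "sampler", f)
    ccfg <- config$classifier
    ccfg$seed <- .childSeed(config$seed, "classifier", f)
    testScores <- switch(config$classifier$kind,
      oracle = as.numeric(labels[testIdx]),
      constant = rep(0.5, length(testIdx)),
      {
        fit <- fitFoldModel(feats, labels, trainIdx, scfg, ccfg)
        predictScores(fit$model,
                      applyMinMax(feats[testIdx, , drop = FALSE],
                                  fit$normalizer))
      })
    yTest <- labels[testIdx]
    perDrug <- split(seq_along(testIdx), pairs$drug[testIdx])
    mapf <- tryCatch(meanAveragePrecision(lapply(perDrug, function(ii)
      list(scores = testScores[ii], labels = yTest[ii]))),
      error = function(e) NA_real_)
    rows[[f]] <- data.frame(fold = f,
                            aupr = computeAUPR(testScores, yTest),
                            auc = computeAUC(testScores, yTest),
                            map = mapf)
    if (isTRUE(config$verbose))
      message(sprintf("fold %d: AUPR %.4f AUC %.4f", f,
                      rows[[f]]$aupr, rows[[f]]$auc))
  }
  folds_df <- do.call(rbind, rows)
  meanAUPR <- mean(folds_df$aupr)
  new("MetricsReport", folds = folds_df,
      summary = list(meanAUPR = meanAUPR, sdAUPR = stats::sd(folds_df$aupr),
                     meanAUC = mean(folds_df$auc),
                     sdAUC = stats::sd(folds_df$auc),
                     er = errorRate(meanAUPR),
                     map = mean(folds_df$map, na.rm = TRUE)))
}

#' Rank novel (unknown) drug-target interactions
#'
#' Trains on all known interactions; the unknown pairs are split over
#' \code{nFolds} folds and each fold's pairs are scored by a model trained
#' on the positives plus the other folds' negatives, so no pair is scored
#' by a model that saw it as a training negative. Known positives never
#' appear in the output. Ties are broken by (drug, target) identifier.
#'
#' @param bundle a \linkS4class{DatasetBundle}
#' @param config a \code{\link{runConfig}}
#' @param topK number of top-ranked candidates to return
#' @return data.frame with columns \code{drug}, \code{target}, \code{score},
#'   sorted by decreasing score; at most \code{min(topK, unknown pairs)} rows
#' @export
predictNovel <- function(bundle, config = runConfig(), topK = 10) {
  dti <- bundle@interactions
  labels <- as.integer(as.vector(dti@values))
  pairs <- buildPairDataset(dti)@pairs
  unknown <- which(labels == 0)
  if (!length(unknown))
    return(data.frame(drug = character(0), target = character(0),
                      score = numeric(0)))
  fused <- .fuseBundle(bundle, config)
  noMask <- pairs[integer(0), , drop = FALSE]
  feats <- .foldFeatures(bundle, fused$dd, fused$tt, noMask, config, 0L)
  set.seed(.childSeed(config$seed, "folds"))
  negFold <- integer(length(labels))
  negFold[unknown] <- rep(seq_len(config$nFolds),
                          length.out = length(unknown))[
                            sample.int(length(unknown))]
  scores <- rep(NA_real_, length(labels))
  for (f in seq_len(config$nFolds)) {
    testIdx <- which(negFold == f)
    trainIdx <- setdiff(seq_along(labels), testIdx)
    scfg <- config$sampler; scfg$seed <- .childSeed(config$seed, "sampler", f)
    ccfg <- config$classifier
    ccfg$seed <- .childSeed(config$seed, "classifier", f)
    fit <- fitFoldModel(feats, labels, trainIdx, scfg, ccfg)
    scores[testIdx] <- predictScores(
      fit$model, applyMinMax(feats[testIdx, , drop = FALSE], fit$normalizer))
  }
  out <- data.frame(drug = pairs$drug[unknown], target = pairs$target[unknown],
                    score = scores[unknown])
  out <- out[order(-out$score, out$drug, out$target), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topK)
}
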