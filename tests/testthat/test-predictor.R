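test_that("pair enumeration labels the complement of the positives", {
  im <- nrShapedInteraction()
  ds <- buildPairDataset(im)
  expect_identical(nrow(pairIndex(ds)), 1404L)
  expect_identical(sum(pairLabels(ds) == 0), 1314L)
  # positives never appear in the negative set
  posPairs <- pairIndex(ds)[pairLabels(ds) == 1, ]
  negPairs <- pairIndex(ds)[pairLabels(ds) == 0, ]
  expect_identical(nrow(merge(posPairs, negPairs)), 0L)
  allOnes <- InteractionMatrix(matrix(1, 2, 2,
    dimnames = list(c("d1", "d2"), c("t1", "t2"))))
  expect_identical(sum(pairLabels(buildPairDataset(allOnes)) == 0), 0L)
})

test_that("fold plans are stratified partitions, reproducible under seed", {
  labels <- c(rep(1L, 23), rep(0L, 177))
  f1 <- makeFoldPlan(labels, 10, seed = 3)
  expect_identical(makeFoldPlan(labels, 10, seed = 3), f1)
  expect_false(identical(makeFoldPlan(labels, 10, seed = 4), f1))
  expect_setequal(unique(f1), 1:10)
  # per-class fold counts differ by at most one pair
  expect_lte(diff(range(table(f1[labels == 1]))), 1)
  expect_lte(diff(range(table(f1[labels == 0]))), 1)
})

test_that("oversampling equalizes classes; random duplicates, SMOTE interpolates", {
  set.seed(8)
  x <- matrix(runif(220), 110, 2)
  y <- c(rep(1L, 10), rep(0L, 100))
  outR <- oversamplePairs(x, y, samplerConfig("random", seed = 2))
  expect_identical(sum(outR$labels == 1), sum(outR$labels == 0))
  expect_identical(sum(outR$labels == 0), 100L)
  # every synthetic row equals some original minority row
  extra <- outR$features[-seq_len(nrow(x)), , drop = FALSE]
  orig <- x[y == 1, ]
  expect_true(all(apply(extra, 1, function(r)
    any(colSums(abs(t(orig) - r)) == 0))))

  # SMOTE with two minority points and k = 1: new points lie on the segment
  xs <- rbind(c(0, 0), c(1, 1), matrix(5 + runif(20), 10, 2))
  ys <- c(1L, 1L, rep(0L, 10))
  outS <- oversamplePairs(xs, ys, samplerConfig("smote", smoteNeighbors = 1,
                                                seed = 3))
  syn <- outS$features[-seq_len(nrow(xs)), , drop = FALSE]
  expect_true(all(abs(syn[, 1] - syn[, 2]) < 1e-12))   # on y = x
  expect_true(all(syn >= 0 & syn <= 1))
  expect_error(oversamplePairs(x, rep(1L, 110), samplerConfig()), "both classes")
  expect_error(oversamplePairs(xs, ys, samplerConfig("smote", smoteNeighbors = 5)),
               "minority")
})

test_that("all classifier backends score in [0, 1] and are deterministic under seed", {
  set.seed(1)
  n <- 120
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] + 0.3 * runif(n) > 0.6)
  probe <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  for (kind in c("NN", "RF", "AdaBoost")) {
    cfg <- classifierConfig(kind, seed = 5, nTrees = 50, nEstimators = 20,
                            maxit = 50)
    m1 <- fitClassifier(x, y, cfg)
    s1 <- predictScores(m1, probe)
    expect_length(s1, 10)
    expect_true(all(s1 >= 0 & s1 <= 1), label = kind)
    s2 <- predictScores(fitClassifier(x, y, cfg), probe)
    expect_identical(s1, s2, label = paste(kind, "determinism"))
    # the signal feature should matter: training AUC well above chance
    expect_gt(computeAUC(predictScores(m1, x), y), 0.8)
  }
})

test_that("cross-validation calibrates correctly with oracle and constant scorers", {
  b <- smallBundle(seed = 5)
  cfgO <- runConfig(nFolds = 5, seed = 9,
                    classifier = classifierConfig("oracle"),
                    walk = walkConfig(numWalks = 3, walkLength = 10,
                                      dimensions = 16))
  repO <- runCrossValidation(b, cfgO)
  expect_equal(foldMetrics(repO)$aupr, rep(1, 5))
  expect_equal(foldMetrics(repO)$auc, rep(1, 5))

  cfgC <- cfgO; cfgC$classifier <- classifierConfig("constant")
  repC <- runCrossValidation(b, cfgC)
  prevalence <- mean(pairLabels(buildPairDataset(b@interactions)))
  expect_equal(metricsSummary(repC)$meanAUPR, prevalence, tolerance = 0.05)
  expect_equal(metricsSummary(repC)$meanAUC, 0.5, tolerance = 1e-12)
  expect_equal(metricsSummary(repC)$er, 1 - metricsSummary(repC)$meanAUPR)
})

test_that("no test-fold information reaches any train-fitted artifact", {
  set.seed(42)
  g1 <- randomHeteroGraph(8, 6, seed = 1)
  g2 <- randomHeteroGraph(8, 6, seed = 2)
  ds <- extractPairFeatures(g1, g2, normalize = FALSE)
  feats <- pairFeatures(ds)
  labels <- pairLabels(ds)
  folds <- makeFoldPlan(labels, 4, seed = 1)
  trainIdx <- which(folds != 1)
  testIdx <- which(folds == 1)
  scfg <- samplerConfig("random", seed = 7)
  ccfg <- classifierConfig("AdaBoost", nEstimators = 10, seed = 7)
  fitA <- fitFoldModel(feats, labels, trainIdx, scfg, ccfg)

  # plant an extreme marker in every test row; train artifacts must not move
  feats2 <- feats
  feats2[testIdx, ] <- feats2[testIdx, ] + 1e6
  fitB <- fitFoldModel(feats2, labels, trainIdx, scfg, ccfg)
  expect_identical(fitA$normalizer, fitB$normalizer)
  expect_identical(fitA$sampled, fitB$sampled)
  probe <- applyMinMax(feats[trainIdx[1:5], , drop = FALSE], fitA$normalizer)
  expect_identical(predictScores(fitA$model, probe),
                   predictScores(fitB$model, probe))

  # planting a new positive at a test pair changes nothing after masking
  pairs <- pairIndex(ds)
  dt <- g1@dtEdges@values
  free <- which(dt == 0)[1]
  dt2 <- dt; dt2[free] <- 1
  mask <- pairs[free, , drop = FALSE]
  gA <- maskTestEdges(buildHeteroGraph(g1@ddWeights, g1@ttWeights,
                                       InteractionMatrix(dt, rownames(dt),
                                                         colnames(dt))), mask)
  gB <- maskTestEdges(buildHeteroGraph(g1@ddWeights, g1@ttWeights,
                                       InteractionMatrix(dt2, rownames(dt),
                                                         colnames(dt))), mask)
  expect_equal(gA, gB)
})

test_that("novel-interaction ranking excludes known positives and orders by score", {
  b <- smallBundle(seed = 6)
  cfg <- runConfig(nFolds = 3, seed = 4,
                   classifier = classifierConfig("AdaBoost", nEstimators = 10),
                   walk = walkConfig(numWalks = 3, walkLength = 10,
                                     dimensions = 16))
  top <- predictNovel(b, cfg, topK = 15)
  expect_identical(nrow(top), 15L)
  expect_true(all(diff(top$score) <= 0))
  dti <- as.matrix(b@interactions)
  known <- paste(pairIndex(buildPairDataset(b@interactions))$drug,
                 pairIndex(buildPairDataset(b@interactions))$target)[
                   as.vector(dti) == 1]
  expect_false(any(paste(top$drug, top$target) %in% known))

  # output is capped by the number of unknown pairs; none -> empty
  allOnes <- DatasetBundle(
    InteractionMatrix(matrix(1, 2, 2,
      dimnames = list(c("d1", "d2"), c("t1", "t2")))),
    drugSims = list(v = SimilarityMatrix(matrix(c(1, .5, .5, 1), 2, 2),
                                         ids = c("d1", "d2"))),
    targetSims = list(v = SimilarityMatrix(matrix(c(1, .4, .4, 1), 2, 2),
                                           ids = c("t1", "t2"))))
  expect_identical(nrow(predictNovel(allOnes, cfg, topK = 5)), 0L)
})
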