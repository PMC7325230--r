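test_that("GIP kernel matches direct evaluation of the Gaussian profile formula", {
  # two drugs with orthogonal unit profiles: gamma = 1, K12 = exp(-2)
  im <- InteractionMatrix(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  k <- gipKernel(im, "drugs")
  expect_equal(as.matrix(k)["a", "b"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(as.matrix(k)), c(a = 1, b = 1))

  # identical profiles give similarity exactly 1
  im2 <- InteractionMatrix(matrix(c(1, 1, 0, 0), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(as.matrix(gipKernel(im2, "drugs"))["a", "b"], 1)

  # target axis equals drug axis on the transpose
  kT <- gipKernel(im, "targets")
  expect_equal(as.matrix(kT)["x", "y"], exp(-2), tolerance = 1e-12)

  empty <- InteractionMatrix(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  expect_error(gipKernel(empty, "drugs"), "bandwidth")
})

test_that("AVG/GeoM/MAX integrate elementwise and fix identical views", {
  ids <- c("a", "b")
  v1 <- simMat(matrix(c(0, .2, .2, 0), 2, 2), ids)
  v2 <- simMat(matrix(c(0, .4, .4, 0), 2, 2), ids)
  expect_equal(as.matrix(integrateSimilarities(list(v1, v2), "AVG"))["a", "b"], 0.3)
  expect_equal(as.matrix(integrateSimilarities(list(v1, v2), "MAX"))["a", "b"], 0.4)
  g1 <- simMat(matrix(c(0, .25, .25, 0), 2, 2), ids)
  g2 <- simMat(matrix(c(0, 1, 1, 0), 2, 2), ids)
  expect_equal(as.matrix(integrateSimilarities(list(g1, g2), "GeoM"))["a", "b"], 0.5)
  for (m in c("AVG", "GeoM", "MAX"))
    expect_equal(as.matrix(integrateSimilarities(list(v1, v1, v1), m)),
                 as.matrix(v1))
  v3 <- simMat(matrix(c(0, .4, .4, 0), 2, 2), c("a", "c"))
  expect_error(integrateSimilarities(list(v1, v3), "AVG"), "identifiers")
})

test_that("integration methods are permutation-equivariant and stay in [0, 1]", {
  set.seed(21)
  ids <- paste0("e", 1:5)
  mk <- function() {
    v <- matrix(runif(25), 5, 5); v <- (v + t(v)) / 2; diag(v) <- 0
    simMat(v, ids)
  }
  views <- list(mk(), mk())
  perm <- sample(5)
  permute <- function(s) simMat(as.matrix(s)[perm, perm], ids[perm])
  for (m in c("AVG", "GeoM", "MAX", "SNF")) {
    f <- as.matrix(integrateSimilarities(views, m, snfK = 3))
    fp <- as.matrix(integrateSimilarities(lapply(views, permute), m, snfK = 3))
    expect_equal(fp, f[perm, perm], tolerance = 1e-9, label = m)
    expect_true(max(abs(f - t(f))) < 1e-9)
    expect_true(min(f) >= 0 && max(f) <= 1)
  }
})

test_that("SNF matches a literal hand iteration of the cross-diffusion update", {
  # independent naive re-implementation with explicit loops
  ids <- c("a", "b", "c")
  w1 <- matrix(c(0, .9, .2, .9, 0, .8, .2, .8, 0), 3, 3)
  w2 <- matrix(c(0, .7, .3, .7, 0, .6, .3, .6, 0), 3, 3)
  naiveSNF <- function(Ws, K, t) {
    k <- nrow(Ws[[1]])
    nf <- function(w) {
      p <- matrix(0, k, k)
      for (i in 1:k) {
        rs <- sum(w[i, -i])
        for (j in 1:k) p[i, j] <- if (i == j) 0.5 else
          if (rs > 0) w[i, j] / (2 * rs) else 0
      }
      p
    }
    nl <- function(w) {
      s <- matrix(0, k, k)
      for (i in 1:k) {
        nb <- setdiff(order(w[i, ], decreasing = TRUE), i)[1:K]
        tot <- sum(w[i, nb])
        if (tot > 0) s[i, nb] <- w[i, nb] / tot
      }
      s
    }
    P <- lapply(Ws, nf); S <- lapply(Ws, nl)
    for (it in 1:t) {
      Pn <- P
      for (v in seq_along(Ws)) {
        others <- Reduce(`+`, P[-v]) / (length(Ws) - 1)
        q <- S[[v]] %*% others %*% t(S[[v]])
        q <- (q + t(q)) / 2
        diag(q) <- 0
        Pn[[v]] <- nf(q)
      }
      P <- Pn
    }
    fused <- Reduce(`+`, P) / length(Ws)
    fused <- (fused + t(fused)) / 2
    diag(fused) <- 0
    fused / max(fused)
  }
  got <- as.matrix(snfFuse(list(simMat(w1, ids), simMat(w2, ids)), K = 2, t = 1))
  expect_equal(got, `dimnames<-`(naiveSNF(list(w1, w2), 2, 1), list(ids, ids)),
               tolerance = 1e-12)
  got20 <- as.matrix(snfFuse(list(simMat(w1, ids), simMat(w2, ids)), K = 2, t = 20))
  expect_equal(got20, `dimnames<-`(naiveSNF(list(w1, w2), 2, 20), list(ids, ids)),
               tolerance = 1e-9)
})

test_that("SNF returns a single view unchanged and validates its arguments", {
  v <- simMat(matrix(c(0, .5, .5, 0), 2, 2), c("a", "b"))
  expect_identical(snfFuse(list(v)), v)
  one <- SimilarityMatrix(matrix(1, 1, 1), ids = "a", diagonal = "unit")
  expect_error(snfFuse(list(one, one)), "at least two entities")
  expect_error(snfFuse(list(v, v), K = 5), "K must be")
})

test_that("SNF on identical clustered views preserves the planted block structure", {
  set.seed(9)
  n <- 8; cl <- rep(1:2, each = 4)
  w <- ifelse(outer(cl, cl, "=="), 0.85, 0.15) + matrix(rnorm(n * n, 0, .03), n, n)
  w <- pmin(pmax((w + t(w)) / 2, 0), 1); diag(w) <- 0
  s <- simMat(w, paste0("e", 1:n))
  f <- as.matrix(snfFuse(list(s, s), K = 3, t = 20))
  within <- f[outer(cl, cl, "==") & row(f) != col(f)]
  between <- f[outer(cl, cl, "!=")]
  expect_gt(mean(within), mean(between))
  # strongest partner agreement survives fusion in the block setting
  expect_gt(min(within), max(between))
})

test_that("forward similarity selection finds planted-informative views and stops correctly", {
  b <- makeSyntheticBenchmark(synthConfig(nInformativeViews = 1,
                                          nNoiseViews = 1, seed = 7))
  ev <- makeLinkEvaluator(b, seed = 7)
  sel <- forwardSimilaritySelection(b@drugSims, b@targetSims, ev)
  expect_identical(sel@selectedDrugViews[1], "informative_1")
  expect_identical(sel@selectedTargetViews[1], "informative_1")
  expect_true(all(diff(sel@scores) > 0) || length(sel@scores) == 1)

  # one view per side: selected after a single round
  b1 <- makeWorkedToy()
  ev1 <- function(dd, tt) 0.5
  sel1 <- forwardSimilaritySelection(b1@drugSims, b1@targetSims, ev1)
  expect_identical(sel1@selectedDrugViews, "main")
  expect_length(sel1@trace, 1)

  # constant evaluator on multiple views: exactly 2 rounds, size 1 per side
  selC <- forwardSimilaritySelection(b@drugSims, b@targetSims,
                                     function(dd, tt) 0.5)
  expect_length(selC@trace, 2)
  expect_length(selC@selectedDrugViews, 1)
  expect_length(selC@selectedTargetViews, 1)

  # evaluator failures carry round context
  expect_error(forwardSimilaritySelection(b@drugSims, b@targetSims,
                                          function(dd, tt) stop("boom")),
               "round 1")
})
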