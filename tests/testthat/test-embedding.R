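test_that("p=q=1 second-order transitions equal first-order weighted-walk probabilities", {
  g <- fiveNodeGraph()
  cfg <- walkConfig(p = 1, q = 1)
  el <- asEdgeList(g)
  # exhaustive over every directed (prev -> cur) edge of the graph
  edges <- rbind(el[, c("node1", "node2")],
                 setNames(el[, c("node2", "node1")], c("node1", "node2")))
  for (i in seq_len(nrow(edges))) {
    p2 <- biasedStepProbabilities(g, edges$node1[i], edges$node2[i], cfg)
    p1 <- biasedStepProbabilities(g, NULL, edges$node2[i], cfg)
    expect_equal(p2, p1[names(p2)], tolerance = 1e-12)
  }
})

test_that("a large in-out parameter suppresses outward steps on a path graph", {
  # path drug:a - target:b - target:c; at b coming from a, stepping on to c
  # carries bias 1/q -> probability vanishes as q grows
  dd <- matrix(0, 1, 1)
  tt <- matrix(c(0, .8, .8, 0), 2, 2)
  dt <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("b", "c")))
  g <- buildHeteroGraph(simMat(dd, "a"), simMat(tt, c("b", "c")),
                        InteractionMatrix(dt))
  pr <- biasedStepProbabilities(g, "drug:a", "target:b",
                                walkConfig(p = 1, q = 1e6))
  expect_lt(pr[["target:c"]], 1e-5)
  expect_gt(pr[["drug:a"]], 1 - 1e-5)
  # and the exact alpha form: w/q over (w/q + w_return/p)
  pr2 <- biasedStepProbabilities(g, "drug:a", "target:b",
                                 walkConfig(p = 2, q = 4))
  expect_equal(pr2[["target:c"]], (.8 / 4) / (.8 / 4 + 1 / 2), tolerance = 1e-12)
})

test_that("walks start at their source, respect the length cap, and reproduce under seed", {
  g <- fiveNodeGraph()
  cfg <- walkConfig(numWalks = 3, walkLength = 7, seed = 4)
  walks <- generateBiasedWalks(g, cfg)
  expect_length(walks, 5 * 3)   # all five nodes have edges
  starts <- vapply(walks, `[`, character(1), 1)
  expect_setequal(unique(starts),
                  c(paste0("drug:", drugNames(g)),
                    paste0("target:", targetNames(g))))
  expect_true(all(lengths(walks) <= 7))
  expect_identical(generateBiasedWalks(g, cfg), walks)
  # isolated nodes are skipped
  lonely <- buildHeteroGraph(
    simMat(matrix(0, 2, 2), c("d1", "d2")),
    simMat(matrix(c(0, .5, .5, 0), 2, 2), c("t1", "t2")),
    InteractionMatrix(matrix(c(1, 0, 0, 0), 2, 2,
      dimnames = list(c("d1", "d2"), c("t1", "t2")))))
  w2 <- generateBiasedWalks(lonely, cfg)
  expect_false("drug:d2" %in% unlist(w2))
})

test_that("empirical walk transitions follow the alpha-biased law (chi-square)", {
  g <- fiveNodeGraph()
  cfg <- walkConfig(p = 0.5, q = 2, numWalks = 30, walkLength = 40, seed = 11)
  walks <- generateBiasedWalks(g, cfg)
  trans <- list()
  for (w in walks) if (length(w) >= 3) for (i in 3:length(w)) {
    key <- paste(w[i - 2], w[i - 1], sep = "|")
    trans[[key]] <- c(trans[[key]], w[i])
  }
  stat <- 0; df <- 0
  for (key in names(trans)) {
    pc <- strsplit(key, "|", fixed = TRUE)[[1]]
    pr <- biasedStepProbabilities(g, pc[1], pc[2], cfg)
    if (length(pr) < 2) next
    obs <- table(factor(trans[[key]], levels = names(pr)))
    stat <- stat + sum((obs - sum(obs) * pr)^2 / (sum(obs) * pr))
    df <- df + length(pr) - 1
  }
  expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("embeddings separate disconnected cliques and are deterministic", {
  ddc <- matrix(0, 6, 6); ddc[1:3, 1:3] <- .9; ddc[4:6, 4:6] <- .9
  diag(ddc) <- 0
  ttc <- matrix(.8, 2, 2); diag(ttc) <- 0
  dtc <- matrix(0, 6, 2, dimnames = list(paste0("d", 1:6), paste0("t", 1:2)))
  dtc[1, 1] <- 1; dtc[4, 2] <- 1
  g <- buildHeteroGraph(simMat(ddc, paste0("d", 1:6)),
                        simMat(ttc, paste0("t", 1:2)),
                        InteractionMatrix(dtc))
  cfg <- walkConfig(seed = 11, dimensions = 16)
  res <- embedGraph(g, cfg)
  expect_identical(ncol(res$embeddings), 16L)
  M <- as.matrix(res$Md)
  intra <- c(M[1:3, 1:3][upper.tri(diag(3))], M[4:6, 4:6][upper.tri(diag(3))])
  inter <- as.vector(M[1:3, 4:6])
  expect_gt(mean(intra), mean(inter))
  # same seed, same table
  expect_identical(embedGraph(g, cfg)$embeddings, res$embeddings)
  # requesting more dimensions than the vocabulary pads with zeros
  small <- trainEmbeddings(list(c("a", "b"), c("b", "a")),
                           walkConfig(dimensions = 8, window = 1))
  expect_identical(dim(small), c(2L, 8L))
})

test_that("cosine similarity matrices obey range, symmetry and scale invariance", {
  emb <- rbind(a = c(1, 0, 0), b = c(2, 0, 0), c = c(0, 1, 0),
               d = c(-1, 0, 0), e = c(0, 0, 0))
  cs <- as.matrix(cosineSimilarityMatrix(emb, c("a", "b", "c", "d", "e")))
  expect_equal(cs["a", "b"], 1)          # identical direction
  expect_equal(cs["a", "c"], 0)          # orthogonal
  expect_equal(cs["a", "d"], 0)          # negative cosine clipped to 0
  expect_equal(cs["a", "e"], 0)          # zero vector
  expect_equal(diag(cs), setNames(rep(0, 5), rownames(emb)))  # graph diag
  # scaling a vector leaves its row unchanged
  emb2 <- emb; emb2["c", ] <- emb2["c", ] * 3
  expect_equal(as.matrix(cosineSimilarityMatrix(emb2, rownames(emb))), cs)
  expect_true(max(abs(cs - t(cs))) == 0 && min(cs) >= 0 && max(cs) <= 1)
  expect_error(cosineSimilarityMatrix(emb, c("a", "zz")), "zz")
})

test_that("embeddings round-trip through the word2vec text format", {
  set.seed(2)
  emb <- matrix(rnorm(12), 3, 4, dimnames = list(c("n1", "n2", "n3"), NULL))
  f <- withr::local_tempfile(fileext = ".txt")
  writeEmbeddings(emb, f)
  expect_identical(readLines(f)[1], "3 4")
  back <- readEmbeddings(f)
  expect_equal(back, emb, tolerance = 1e-15)
})
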