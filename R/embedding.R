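#' Random-walk and embedding configuration
#'
#' Parameters of the second-order biased random walks and of the embedding
#' trained from them. \code{p} is the return parameter (likelihood of
#' immediately revisiting the previous node), \code{q} the in-out parameter
#' (inward vs outward exploration); the customary search grid for both is
#' {0.25, 0.5, 1, 2, 4} and for \code{dimensions} {16, 32, 64, 128}.
#'
#' @param p,q positive bias parameters; defaults 1 (unbiased)
#' @param dimensions embedding dimensionality, default 64
#' @param numWalks walks started per node, default 10
#' @param walkLength maximum walk length, default 30
#' @param window context window for co-occurrence, default 5
#' @param seed integer RNG seed
#' @return a \code{walkConfig} list
#' @export
walkConfig <- function(p = 1, q = 1, dimensions = 64, numWalks = 10,
                       walkLength = 30, window = 5, seed = 1) {
  stopifnot(p > 0, q > 0, dimensions >= 1, numWalks >= 1, walkLength >= 1,
            window >= 1)
  structure(list(p = p, q = q, dimensions = dimensions, numWalks = numWalks,
                 walkLength = walkLength, window = window,
                 seed = as.integer(seed)),
            class = "walkConfig")
}

# Combined weighted adjacency of the heterogeneous graph; nodes are
# namespaced "drug:<id>" / "target:<id>".
.graphAdjacency <- function(g) {
  dd <- g@ddWeights@values
  tt <- g@ttWeights@values
  dt <- g@dtEdges@values
  n <- nrow(dd); m <- nrow(tt)
  nodes <- c(paste0("drug:", rownames(dd)), paste0("target:", rownames(tt)))
  w <- matrix(0, n + m, n + m, dimnames = list(nodes, nodes))
  w[seq_len(n), seq_len(n)] <- dd
  w[n + seq_len(m), n + seq_len(m)] <- tt
  w[seq_len(n), n + seq_len(m)] <- dt
  w[n + seq_len(m), seq_len(n)] <- t(dt)
  w
}

#' Second-order transition probabilities of the biased walk
#'
#' The probability of stepping from \code{cur} to each neighbour x, having
#' arrived from \code{prev}, is proportional to w(cur, x) * alpha where
#' alpha = 1/p when x = prev, 1 when x is adjacent to prev, and 1/q
#' otherwise. Exposed so walk statistics can be checked against the exact
#' law.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @param prev,cur namespaced node names (\code{"drug:<id>"} /
#'   \code{"target:<id>"}); \code{prev = NULL} gives the first-order
#'   (weight-proportional) law
#' @param cfg a \code{\link{walkConfig}}
#' @return named probability vector over the neighbours of \code{cur}
#' @export
biasedStepProbabilities <- function(g, prev, cur, cfg = walkConfig()) {
  w <- .graphAdjacency(g)
  stopifnot(cur %in% rownames(w))
  wts <- w[cur, ]
  nbr <- which(wts > 0)
  if (!length(nbr)) stop("node has no neighbours: ", cur)
  wts <- wts[nbr]
  if (!is.null(prev)) {
    alpha <- ifelse(names(wts) == prev, 1 / cfg$p,
                    ifelse(w[prev, names(wts)] > 0, 1, 1 / cfg$q))
    wts <- wts * alpha
  }
  wts / sum(wts)
}

#' Generate second-order biased random walks
#'
#' Starts \code{numWalks} walks at every non-isolated node of the
#' heterogeneous graph and extends each up to \code{walkLength} steps under
#' the alpha-biased second-order law of
#' \code{\link{biasedStepProbabilities}}. Reproducible under
#' \code{cfg$seed}.
#'
#' @param g a \linkS4class{HeteroGraph} with at least one edge
#' @param cfg a \code{\link{walkConfig}}
#' @return list of character vectors of namespaced node names, each starting
#'   at its source node
#' @export
generateBiasedWalks <- function(g, cfg = walkConfig()) {
  w <- .graphAdjacency(g)
  nN <- nrow(w)
  nbrs <- lapply(seq_len(nN), function(i) which(w[i, ] > 0))
  wts <- lapply(seq_len(nN), function(i) w[i, nbrs[[i]]])
  sources <- which(lengths(nbrs) > 0)
  if (!length(sources)) stop("graph has no edges")
  set.seed(cfg$seed)
  walks <- vector("list", length(sources) * cfg$numWalks)
  k <- 0L
  pick <- function(ids, pr) if (length(ids) == 1L) ids else
    ids[sample.int(length(ids), 1L, prob = pr)]
  for (rep in seq_len(cfg$numWalks)) {
    for (s in sources) {
      walk <- integer(cfg$walkLength)
      walk[1] <- s
      if (cfg$walkLength >= 2) {
        walk[2] <- pick(nbrs[[s]], wts[[s]])
        i <- 2L
        while (i < cfg$walkLength) {
          cur <- walk[i]; prev <- walk[i - 1L]
          cand <- nbrs[[cur]]
          alpha <- ifelse(cand == prev, 1 / cfg$p,
                          ifelse(w[prev, cand] > 0, 1, 1 / cfg$q))
          i <- i + 1L
          walk[i] <- pick(cand, wts[[cur]] * alpha)
        }
      }
      k <- k + 1L
      walks[[k]] <- rownames(w)[walk[walk > 0]]
    }
  }
  walks
}

#' Train node embeddings from random walks
#'
#' Learns one \code{dimensions}-length vector per node appearing in the
#' walks by factorizing the positive pointwise mutual information (PPMI)
#' matrix of windowed walk co-occurrences with a truncated SVD -- the
#' closed-form counterpart of skip-gram training on the same walks. The
#' procedure is deterministic given the walks; sign ambiguity of singular
#' vectors is fixed by orienting each component's largest-magnitude loading
#' positive.
#'
#' @param walks list of node-name vectors from
#'   \code{\link{generateBiasedWalks}}
#' @param cfg a \code{\link{walkConfig}} (uses \code{window} and
#'   \code{dimensions})
#' @return numeric matrix with one named row per node (the embedding table)
#' @export
trainEmbeddings <- function(walks, cfg = walkConfig()) {
  if (!length(walks)) stop("no walks supplied")
  vocab <- sort(unique(unlist(walks)))
  V <- length(vocab)
  keys <- vector("list", length(walks) * cfg$window)
  k <- 0L
  for (walk in walks) {
    idx <- match(walk, vocab)
    L <- length(idx)
    for (off in seq_len(min(cfg$window, L - 1L))) {
      a <- idx[seq_len(L - off)]
      b <- idx[seq_len(L - off) + off]
      k <- k + 1L
      keys[[k]] <- c(a + (b - 1L) * V, b + (a - 1L) * V)
    }
  }
  counts <- tabulate(unlist(keys[seq_len(k)]), nbins = V * V)
  X <- matrix(as.numeric(counts), V, V)
  tot <- sum(X)
  rs <- rowSums(X)
  pmi <- log(X * tot) - log(outer(rs, rs))
  pmi[X == 0] <- 0
  ppmi <- pmax(pmi, 0)
  sv <- svd(ppmi)
  d <- min(cfg$dimensions, V)
  emb <- sv$u[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(d)]), d, d)
  for (j in seq_len(d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) emb[, j] <- -emb[, j]
  }
  if (d < cfg$dimensions)
    emb <- cbind(emb, matrix(0, V, cfg$dimensions - d))
  rownames(emb) <- vocab
  emb
}

#' Cosine-similarity matrix from an embedding table
#'
#' Entry (a, b) is the cosine of the corresponding embedding vectors,
#' clipped below at 0 so the result satisfies the (0, 1] edge-weight
#' contract of the heterogeneous graph; the diagonal is zero for graph use.
#' Vectors of zero norm get similarity 0 to every node.
#'
#' @param emb embedding matrix with named rows
#' @param ids node names to extract, in order
#' @param outputIds optional identifiers for the result (e.g. bare drug ids
#'   when \code{ids} are namespaced); default \code{ids}
#' @return a zero-diagonal \linkS4class{SimilarityMatrix}
#' @export
cosineSimilarityMatrix <- function(emb, ids, outputIds = ids) {
  missing <- setdiff(ids, rownames(emb))
  if (length(missing))
    stop("nodes missing from embedding table: ",
         paste(missing, collapse = ", "))
  v <- emb[ids, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  nz <- nrm > 0
  v[nz, ] <- v[nz, , drop = FALSE] / nrm[nz]
  cs <- tcrossprod(v)
  cs[!nz, ] <- 0
  cs[, !nz] <- 0
  cs <- pmin(pmax(cs, 0), 1)
  SimilarityMatrix(cs, ids = outputIds, diagonal = "zero")
}

#' Embed a heterogeneous graph and derive cosine similarity matrices
#'
#' Convenience wrapper: generates biased walks over the graph, trains node
#' embeddings, and returns the drug-drug and target-target cosine matrices
#' M_d and M_t used to build the embedding-derived graph G2. Nodes that are
#' isolated in the graph (hence absent from every walk) get zero similarity
#' to every other node.
#'
#' @param g a \linkS4class{HeteroGraph}
#' @param cfg a \code{\link{walkConfig}}
#' @return list with elements \code{Md}, \code{Mt}
#'   (\linkS4class{SimilarityMatrix}, zero diagonal) and \code{embeddings}
#' @export
embedGraph <- function(g, cfg = walkConfig()) {
  walks <- generateBiasedWalks(g, cfg)
  emb <- trainEmbeddings(walks, cfg)
  allNodes <- c(paste0("drug:", drugNames(g)), paste0("target:", targetNames(g)))
  absent <- setdiff(allNodes, rownames(emb))
  if (length(absent)) {
    emb <- rbind(emb, matrix(0, length(absent), ncol(emb),
                             dimnames = list(absent, NULL)))
  }
  list(Md = cosineSimilarityMatrix(emb, paste0("drug:", drugNames(g)),
                                   outputIds = drugNames(g)),
       Mt = cosineSimilarityMatrix(emb, paste0("target:", targetNames(g)),
                                   outputIds = targetNames(g)),
       embeddings = emb)
}

#' Persist embeddings in word2vec text format
#'
#' First line \code{"<count> <dim>"}, then one node per line: name followed
#' by its vector components, space-separated.
#'
#' @param emb embedding matrix with named rows
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeEmbeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1, function(r) paste(format(r, digits = 17),
                                                   collapse = " "))), con)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @param path file written by \code{writeEmbeddings}
#' @return \code{readEmbeddings}: the embedding matrix
#' @export
readEmbeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " +")
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(emb) <- vapply(parts, `[`, character(1), 1)
  emb
}
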