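---
title: "Methods: heterogeneous-network DTI prediction in dtigems"
author: "dtigems authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-network DTI prediction in dtigems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

dtigems treats drug–target interaction (DTI) prediction as link prediction
in a weighted heterogeneous graph over n drug and m target nodes. Known
interactions are edges of weight exactly 1; drug–drug and target–target
similarity edges carry weights in (0, 1]. The guiding assumption is
guilt-by-association: similar drugs tend to share targets and vice versa,
so the existence of short, heavily weighted paths from a drug to a target
is evidence for an interaction. Every (drug, target) pair is a binary
classification instance; the negative class is the complement of the known
positives (no experimentally validated negatives exist at this scale, and
with sparsity ratios around 0.01–0.07 the contamination of the complement
by undiscovered positives is modest).

Two graphs supply complementary evidence. *G1* carries the fused
precomputed similarity views — chemistry, side effects, sequence, ontology,
whatever kernels the dataset ships — while *G2* carries cosine similarities
between node embeddings of the interaction-augmented graph and therefore
purely topological information. Features extracted from both are
concatenated, so the classifier sees each source separately.

# Stages and their parameters

## Similarity integration

`integrateSimilarities()` supports AVG, GeoM, MAX and SNF. SNF
(`snfFuse()`) is the default: each view is converted to a row-stochastic
full kernel P (half of each row's mass on the diagonal, the published
normalization) and a KNN-restricted local kernel S; the update
P⁽ᵛ⁾ ← S⁽ᵛ⁾ · mean(P⁽ᵘ⁾)ᵤ≠ᵥ · S⁽ᵛ⁾ᵀ runs for `snfT = 20` iterations
with symmetrization and renormalization after each step, and the average of
the final kernels is rescaled so its largest off-diagonal entry is 1.
`snfK` defaults to min(20, k − 1) neighbours — the convention of the
algorithm's reference implementation; both values matter little once the
diffusion has converged, which happens within a handful of iterations on
the sizes used here. A single view is returned unchanged.

One property worth stating explicitly because it is easy to assume
otherwise: cross-diffusion does *not* preserve the exact within-row
neighbour ranking of the input, even when all views are identical. The
update rewards pairs with strong shared neighbourhoods, so two entries can
swap order while the coarse (cluster-level) structure sharpens. The test
suite therefore pins SNF to an independent hand-iteration of the update and
to cluster-separation properties, not to rank identity.

## Gaussian interaction-profile kernel

`gipKernel()` computes K(a, b) = exp(−γ‖y_a − y_b‖²) on interaction-profile
rows (drugs) or columns (targets), with bandwidth γ = γ̃ / meanₐ‖y_a‖² and
γ̃ = 1, the original formulation's default (no published value overrides
it). An all-zero interaction matrix leaves the bandwidth undefined and is
rejected. Two entities with no interactions at all have identical (zero)
profiles and thus kernel value 1 — acceptable for the kernel's role as one
view among several.

## Forward similarity selection

`forwardSimilaritySelection()` scans all (drug view, target view) pairs in
round one, then adds one view per side per round, scoring each candidate's
SNF fusion with a caller-supplied evaluator and stopping when the gain
drops to `epsilon = 1e-4` AUPR ("no improvement" needs a number; at 1e-4
the stop is insensitive to evaluator noise an order of magnitude smaller).
Ties break lexicographically by view name so reruns are identical. The
default evaluator (`makeLinkEvaluator()`) holds out 20% of known
interactions, masks them, and ranks all non-training pairs by the sum of
the D–D–T, D–T–T and D–D–T–T path Sum scores — a deliberately cheap proxy
for the full pipeline that preserves the ordering of informative versus
noise views while keeping selection inside training data (selection on
held-out *test* folds would leak; the stricter inner-validation reading is
the one implemented).

## Graph sparsification and embedding

`knnSparsify()` keeps each node's `k = 5` strongest neighbours
(symmetric union; ties at the k-th value are all kept so the operation is
deterministic and idempotent). Five neighbours retains the cluster
backbone of graphs with tens to hundreds of nodes while cutting the edge
count to at most k·n; the value is configurable and should grow with graph
size. Only the embedding-input graph G is sparsified by default; G1 and G2
keep dense similarities, since path-score features benefit from the full
weight structure while walk-based embedding benefits from noise removal.

`generateBiasedWalks()` implements the second-order biased walk: from
current node v, having arrived from u, the step to x is proportional to
w(v, x)·α with α = 1/p if x = u, 1 if x is adjacent to u, 1/q otherwise.
Defaults p = q = 1, `numWalks = 10`, `walkLength = 30`, `window = 5`,
`dimensions = 64` — mid-grid values of the customary search ranges
({0.25, 0.5, 1, 2, 4} for p, q; {16, 32, 64, 128} for d; walk lengths
10–60 for small graphs). Transitions are sampled directly from the
normalized categorical law; any sampler matching that law is equivalent,
and the chi-square test in the suite checks the realized frequencies
against the exact probabilities.

`trainEmbeddings()` factorizes the positive pointwise-mutual-information
matrix of windowed walk co-occurrences by truncated SVD (vectors
U·diag(√σ)), the closed-form counterpart of skip-gram training on the same
walks. It is exactly deterministic given the walks — no SGD noise — which
makes the per-fold embeddings reproducible from the top-level seed alone;
singular-vector sign ambiguity is fixed by orienting each component's
largest loading positive. Cosine similarities are clipped below at 0
(`cosineSimilarityMatrix()`): a negative cosine means "less than unrelated",
which the (0, 1] edge-weight contract cannot express, and clipping to zero
simply omits the edge. Embeddings are recomputed inside every
cross-validation fold on the masked graph; reusing embeddings trained on
the full graph would leak test edges through the walk statistics.

## Meta-path score features

For each of the six structures (C1: D–D–T, C2: D–T–T, C3: D–D–D–T,
C4: D–T–T–T, C5: D–D–T–T, C6: D–T–D–T) and each pair, the Sum feature is
the sum of edge-weight products over all *simple* paths of that shape and
the Max feature is the largest single product. `sumScoreMatrix()` and
`maxScoreMatrix()` compute these by chained ordinary and max-times matrix
products. Simplicity is enforced exactly:

* zero diagonals on the similarity layers remove immediate revisits;
* C3 walks d–x–d–t and C4 walks d–t′–t″–t′ are removed by zeroing the
  diagonal of the squared similarity factor before the final product;
* C6 walks reusing the end drug or target are removed by
  inclusion–exclusion (subtract the row- and column-degree terms, add back
  the doubly-counted d–t–d–t walk). Because drug–target edges all carry
  weight 1, every simple C6 path has product exactly 1, and the C6 Max
  score reduces to the indicator that the C6 Sum is positive.

The binding correctness contract is agreement with
`enumerateSimplePathScores()`, a brute-force loop enumeration, to 1e-9 on
randomized graphs; the matrix chains were derived from the structure
definitions and are pinned by that oracle rather than by any published
chain table. Scores from different structures are never mixed in one
feature; each column is min–max normalized, with the fit population being
the training pairs only (the fit is applied to test pairs with clipping to
[0, 1]) — fitting on all pairs would leak test-fold score magnitudes.
Constant columns map to 0. The four C6 columns are dropped by default:
they are built from the sparse known-interaction layer alone and carry
little signal; `selectFeatures()` can also run greedy forward selection
over the remaining columns.

## Imbalance handling and classifiers

`oversamplePairs()` equalizes classes on training data only: random
oversampling duplicates minority rows; SMOTE interpolates between a
minority row and one of its `smoteNeighbors = 5` nearest minority
neighbours. Classifiers: single-hidden-layer perceptron (`nnet`, 16 hidden
units, weight decay 1e-3), random forest (`randomForest`, 300 trees), and
discrete AdaBoost (SAMME) over depth-2 `rpart` trees (50 rounds),
implemented in-package. The `"auto"` kind uses the perceptron below 2000
pairs — small, high-variance datasets favour it — and AdaBoost otherwise,
matching how the classifiers rank on small versus larger DTI benchmarks.
All stochastic stages draw their seeds from one top-level seed through a
fixed integer fan-out, so a run is a pure function of (data, config, seed).

## Cross-validation protocol

`runCrossValidation()` assigns all n·m pairs to ten stratified folds
(per-class counts per fold within one pair). Per fold, the test positives
are masked from the interaction layer *before* G, G1 and G2 are built, the
embedding is retrained, features are extracted, and the normalizer,
sampler and classifier are fitted on training rows only. The leak-freedom
canary in the suite perturbs test rows with a sentinel value and asserts
the train-fitted artifacts are bit-identical. `predictNovel()` follows the
companion protocol for ranking unknown pairs: the model trains on all
positives while the negatives are split over folds, so every unknown pair
is scored by a model that never saw it as a training negative.

## Metrics

`computeAUPR()` is the average-precision (step-curve) estimator evaluated
at every distinct score threshold; trapezoidal interpolation is avoided
because it over-estimates precision–recall areas, and thresholding makes
the result invariant to monotone score transforms and well-defined under
ties. `computeAUC()` is the midrank Mann–Whitney statistic (ties count ½).
ER = 1 − AUPR and ΔER = (ER₂ − ER₁)/ER₂ are carried as fractions
internally and formatted as percentages only at reporting. Mean average
precision averages per-drug AP over drugs with at least one positive;
drugs without positives are excluded (AP is undefined for them) rather
than counted as zero.

# The synthetic benchmark: what it shows and what it cannot

`makeSyntheticBenchmark()` plants paired drug/target clusters: informative
similarity views draw within-cluster entries from a truncated Gaussian
N(0.8, 0.05) and between-cluster entries from N(0.2, 0.05); noise views are
cluster-independent; interactions are Bernoulli(0.3) for matched-cluster
pairs and Bernoulli(0.01) otherwise. Defaults: 60 drugs, 40 targets, 4
clusters, 2 informative + 1 noise view per side, seed 42, giving a realized
sparsity ratio near 0.09. The block design realizes guilt-by-association
directly, so every stage — fusion, selection, embedding, path scores — has
a detectable signal, and truncated Gaussian noise is the simplest
perturbation that keeps similarities in [0, 1].

What passing tests show: the pipeline recovers planted structure (AUC and
MAP well above chance), forward selection reliably prefers informative
views, and no stage leaks test information. What they cannot show: because
interactions are conditionally independent given cluster membership, a
masked test edge is statistically indistinguishable from a matched-block
negative, so the Bayes-optimal ranking is block membership and its average
precision equals the within-block interaction density (≈ 0.3 at the
defaults). The suite verifies the pipeline meets this oracle ceiling
(block-membership oracle with the true clusters, same folds) rather than
any higher figure; real kernels, whose fine structure correlates with
individual interactions rather than only with block membership, are what
higher absolute AUPR values depend on. The generator also does not imitate
real kernel value distributions, hub-degree skew, or cold-start drugs.

# Degenerate inputs and numerical conventions

* Similarity files: asymmetries ≤ 1e-6 are averaged away, larger ones are
  errors; entries outside [0, 1] beyond 1e-9 are errors; the diagonal
  convention (unit for kernels, zero for graphs) is declared per file
  because source files are inconsistent about it.
* The interaction-file reader takes an explicit orientation flag (benchmark
  files ship targets-as-rows) instead of auto-detection, which can misfire
  on square matrices.
* Sum-score corrections can leave values a few ulps below zero; they are
  clamped to 0.
* Isolated nodes are skipped by the walker and enter the cosine matrices
  with similarity 0 to every node.
* KNN ties at the k-th neighbour are all kept; FSS and feature-selection
  ties break lexicographically.
* Identifiers are opaque strings; no accession semantics are parsed.

# Problem sizes

The shipped tests and scripts run the full cross-validated pipeline on the
60×40 default benchmark (ten folds, per-fold re-embedding), path-score
oracle comparisons on 200 random graphs of up to 8×8 entities, and
20-replicate selection experiments — sizes chosen so the complete suite
exercises every stage end-to-end in about a minute on a single core while
leaving the per-stage algorithms identical to what larger datasets would
use.

# Known limitations

* Cold-start prediction (a drug or target with no known interactions) is
  out of scope; GIP profiles and path scores are uninformative there.
* The negative class is the unlabelled complement; no reliable-negative
  construction is attempted.
* Entropy-based similarity filtering (an alternative to FSS) is not
  implemented.
* Paths longer than three edges and unweighted path-count features are not
  computed.
* Per-fold embedding retraining makes cross-validation cost scale linearly
  in folds; on large graphs the walk stage dominates.
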