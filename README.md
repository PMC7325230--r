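# dtigems

Drug–target interaction (DTI) prediction from heterogeneous similarity
networks, for computational chemists and bioinformaticians who have a binary
drug–target interaction matrix plus one or more precomputed drug–drug and
target–target similarity kernels (chemical-structure, side-effect, sequence,
GO, PPI, …) and want calibrated rankings of unknown pairs.

## The method

Prediction is cast as link prediction in a weighted heterogeneous graph
*G(V, E)* over drug nodes *D* = {d₁…dₙ} and target nodes *T* = {t₁…tₘ} with
three edge types: known DTIs (weight 1), drug–drug similarities and
target–target similarities (weights in (0, 1]). The pipeline:

1. **Similarity integration.** Multiple similarity views per side are fused
   by elementwise average (AVG), geometric mean (GeoM), maximum (MAX), or
   similarity network fusion (SNF) — iterative cross-diffusion
   P⁽ᵛ⁾ ← S⁽ᵛ⁾ · mean(P⁽ᵘ⁾)ᵤ≠ᵥ · S⁽ᵛ⁾ᵀ over KNN-restricted local kernels.
   A Gaussian interaction-profile (GIP) kernel
   K(a,b) = exp(−γ‖y_a − y_b‖²), γ = 1 / meanₐ‖y_a‖², can be added as an
   extra view. Greedy forward similarity selection (FSS) picks the view
   subset whose fusion maximizes a validation AUPR.
2. **Node embedding.** Second-order biased random walks (return parameter
   *p*, in–out parameter *q*; transition weight w(v,x)·α with α = 1/p, 1, or
   1/q) are run over the KNN-sparsified graph *G*; node vectors trained from
   the walks yield cosine-similarity matrices M_d (n×n) and M_t (m×m).
3. **Meta-path features.** From graph *G1* (fused similarities + training
   DTIs) and *G2* (cosine similarities + training DTIs), every pair gets the
   Sum and Max of edge-weight products over all *simple* paths of six
   structures — C1: D–D–T, C2: D–T–T, C3: D–D–D–T, C4: D–T–T–T, C5: D–D–T–T,
   C6: D–T–D–T — computed by (max-)product matrix chains with closed-form
   corrections for non-simple walks, then min–max normalized: a
   24-dimensional feature vector (the sparse C6 block is dropped by default,
   leaving 20).
4. **Classification.** Training pairs are rebalanced by random oversampling
   or SMOTE and scored by a neural network, random forest, or AdaBoost,
   inside stratified tenfold cross-validation in which each fold's test DTIs
   are masked from *every* graph before any feature, normalizer, sampler, or
   classifier is fitted.
5. **Evaluation.** AUPR (average precision), AUC, error rate ER = 1 − AUPR,
   relative error-rate reduction ΔER = (ER₂ − ER₁)/ER₂, and mean average
   precision over drugs.

A planted-cluster synthetic generator (`makeSyntheticBenchmark`) makes the
whole pipeline testable offline.

## Worked example

```r
library(dtigems)

toy <- makeWorkedToy()          # 2 drugs, 2 targets, edges DD=0.5, TT=0.4, d2-t1
g <- buildHeteroGraph(toy@drugSims$main, toy@targetSims$main, toy@interactions)
sumScoreMatrix(g, "C1")
#>     t1 t2
#> d1 0.5  0
#> d2 0.0  0
```

The single D–D–T path d1–d2–t1 has product 0.5·1; d2 itself has no C1 path
(its only route would revisit d2). On the default synthetic benchmark:

```r
bundle <- makeSyntheticBenchmark(synthConfig())   # 60 x 40, 4 planted clusters
runCrossValidation(bundle, runConfig(seed = 42))
#> MetricsReport over 10 folds
#>   AUPR 0.3167 +/- 0.0555   AUC 0.8281 +/- 0.0538   ER 0.6833
#>   MAP  0.7875
```

The AUC (0.83) and MAP (0.79) show the planted cluster structure is
recovered; the AUPR is bounded near the within-cluster interaction density
(0.3) because, in this generator, interactions are drawn independently
inside matched cluster blocks, so no ranker can separate a held-out true
edge from a matched-block negative (see the methods vignette for the
ceiling analysis — a block-membership oracle scores 0.27 here).

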