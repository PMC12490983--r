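---
title: "Prioritizing disease risk genes on gene-set hypergraphs"
author: "hyperAD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease risk genes on gene-set hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperAD)
```

## The problem and the model

Most computational gene-prioritization methods propagate risk over
pairwise gene networks. Complex polygenic diseases such as Alzheimer's,
however, are driven by the coordinated action of many genes inside
pathways and functional modules, and that multi-gene structure is
exactly what a pairwise graph cannot represent. hyperAD instead models
annotated gene-set collections (GMT files, e.g. MSigDB's H and C1--C8
collections) as a *hypergraph*: genes are nodes, each gene set is one
hyperedge connecting all of its members, and the N x M binary incidence
matrix `H` records membership, `H[v, e] = 1` iff gene `v` belongs to set
`e`. Node and hyperedge degrees are

$$d(v) = \sum_e w(e)\,H(v,e), \qquad \delta(e) = \sum_v H(v,e),$$

and the normalized hypergraph Laplacian
$\Delta = I - D_v^{-1/2} H W D_e^{-1} H^{\top} D_v^{-1/2}$ (symmetric,
positive semidefinite, annihilating $D_v^{1/2}\mathbf{1}$) is exposed for
spectral diagnostics, with the classical one-shot hypergraph convolution
(`hgnnLayer()`) kept as an architecture-comparison baseline.

The predictive model is a two-stage message-passing network. One-hot
gene inputs are projected into a d-dimensional embedding (realized as a
row lookup, so the N x N one-hot matrix is never formed):
$x_v^{(0)} = \mathrm{ReLU}(x\,\Theta_0 + b_0)$. Each block then runs

1. **node-to-hyperedge**:
   $y_e = \mathrm{ReLU}\big(\sum_{v \in e} \tfrac{x_v}{d(v)}\,\Theta_{v\to e}\big)$ —
   every gene set summarizes its members, degree-normalized so
   promiscuous genes do not dominate;
2. **hyperedge-to-node**:
   $x_v' = \mathrm{ReLU}\big(\sum_{e \ni v} w(e)\, y_e\,\Theta_{e\to v} + x_v\big)$ —
   every gene aggregates its contexts, scaled by the disease-specific
   hyperedge weight, with a residual connection *inside* the activation
   so the gene's own representation is preserved.

A final 2-unit softmax head yields per-gene class probabilities; the
second column is the risk score. Training is transductive full-batch
cross-entropy over the labeled genes only (known risk genes vs sampled
non-risk genes), optimized with Adam; gradients are computed by
hand-written reverse-mode differentiation of exactly this composition,
and a numerical-differentiation test pins the two against each other.

The disease-specific weight is the fraction of a hyperedge's members
that are known risk genes,
$w(e) = |e \cap V_d| \, / \, \delta(e) \in [0,1]$: gene sets dense in
known disease genes shout, unrelated ones whisper ($w=0$ hyperedges are
provably inert — a tested invariant). The `weightMode = "unweighted"`
ablation sets all $w(e)=1$ and consistently underperforms the weighted
model on the planted benchmark, mirroring the motivation for the
weighting.

## Parameters that matter

* `embedDim` (default 128) and `nBlocks` (default 2): capacity of the
  embedding and the radius of hypergraph context each gene sees. Two
  blocks reach genes two hyperedge-hops away, which already covers most
  of a gene-set collection's connected component.
* `learningRate` (1e-3), `epochs` (200): Adam defaults; full-batch
  training on desk-scale hypergraphs converges well before 200 epochs.
* `weightMode`: `"ad_weighted"` (the disease-specific weights above,
  recomputed per CV training fold from the fold's positives only, so
  held-out labels can never leak) or `"unweighted"` for the ablation.
* `degreeNormMode`: the degree $d(v)$ in the node-to-hyperedge stage.
  The general degree definition is weight-dependent, but disease weights
  zero out every hyperedge without a known positive and can therefore
  zero a node's degree mid-normalization; the default `"unweighted"`
  (count of incident hyperedges) is always strictly positive after
  construction and is the numerically safe choice. `"weighted"` is
  available and errors loudly on zero degrees.
* `minSize` in `buildHypergraph()` (default 2): singleton gene sets
  carry no relational information and are dropped; `maxSize` is
  unbounded by default. The gene universe is the union of the retained
  sets' members — there is no external gene catalogue — with genes
  sorted lexicographically and sets kept in input order so every
  downstream matrix is reproducible. Hyperedge-weight denominators use
  the constructed $\delta(e)$, so members lost to the size filter do not
  inflate them.
* Cross-validation (`cvConfig`): 10 repetitions x 5 stratified folds by
  default; negatives are resampled from the pool each repetition
  (`resampleNegatives = FALSE` reuses a single draw — the literature is
  ambiguous on this point, so both are provided). Stratification
  guarantees both classes in every fold at realistic class sizes.
* Validation statistics: the decile test uses the hypergeometric upper
  tail for the first bin of the ranked list (contiguous near-equal bins,
  remainder to earlier bins) with Benjamini--Hochberg control across
  terms; the network test uses size-matched uniform resampling of
  network genes (excluding the known set) with
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$ and
  `nPerm = 10000` by default (resolution $10^{-4}$); the trend test uses
  tie-corrected Kendall tau-b with its normal-approximation p-value and
  BH control across genes. A degree-preserving network null would be a
  reasonable alternative; uniform resampling was chosen as the minimal
  standard construction.

## What the synthetic generators emulate

`generatePlantedHypergraph()` mimics the structure that makes gene-set
collections informative about a disease: a module of disease genes that
co-occurs across many "relevant" gene sets. Relevant hyperedges draw
each member from the disease module with probability
`pDiseaseInRelevant` (default 0.8), background hyperedges draw
uniformly. The default desk-scale conditions — 300 genes, 30 disease
genes, 40 relevant + 120 background sets of 5--25 genes, half the module
exposed as training positives, 100 sampled negatives (about the 1:7
positive:negative ratio typical of curated risk-gene lists vs sampled
non-risk pools) — train in seconds on one CPU while leaving a held-out
half of the module to discover. `generateStagedExpression()` emulates a
cohort stratified into three ordered clinical stages with group sizes
174/100/104 and plants monotone per-stage mean shifts (default 0.5 noise
SDs per step, sign randomized and recorded) in a subset of genes.
`generateToyNetwork()` plants chosen edges into an Erdős--Rényi
background.

What passing on these generators shows — and does not show. The
generators produce exchangeable set sizes, independent memberships,
Gaussian noise and clean labels. Real collections have heavy-tailed set
sizes, nested/redundant sets, correlated annotations, noisy and
incomplete label lists, and batch structure in expression data. Green
tests therefore certify the *mechanics* (equations, leakage-free CV,
calibrated statistics, planted-signal recovery) — not performance on any
real disease dataset.

## Numerical choices and degenerate inputs

* Ranking ties are broken lexicographically by gene symbol, making every
  reported ranking deterministic.
* AUROC is the rank-based (Mann--Whitney) estimator counting ties as
  1/2; AUPRC is step-rule average precision (trapezoidal interpolation
  of PR curves is optimistic and deliberately avoided).
* Softmax is computed with row-max subtraction; log-loss clamps
  probabilities at 1e-300; non-finite intermediates abort with the
  offending block or epoch index.
* Parameters use Xavier-uniform initialization; the configuration seed
  is mandatory, every randomized routine (generators, CV sampling,
  permutation nulls) takes an explicit seed, and two runs with the same
  seed are bit-for-bit identical.
* Constant expression vectors have undefined tau; they are recorded with
  `tau = NA`, `p = 1`, direction `"none"` rather than dropped, so FDR
  control stays honest across the full gene panel. Missing expression is
  handled pairwise-complete per gene.
* Exact tau-b p-values are not attempted: the normal approximation is
  used throughout (the test suite validates it against an exhaustive
  pair-counting oracle with the full tie-corrected variance).
* Genes labeled but absent from the hypergraph are dropped with a
  warning (count reported); an all-filtered gene-set collection, a
  single-class fold, and zero degrees under weighted normalization are
  hard errors with actionable messages.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to exercise the full pipeline
comfortably on a single CPU: oracle comparisons on 50 random hypergraphs
of up to 20 genes x 10 hyperedges; planted-module recovery on the
default 300-gene spec over 5 seeds with the default model; the weighting
ablation over 10 seeds with 1x3-fold CV, 32-dimensional embeddings and
100 epochs; trend-test power at the default 174/100/104 staged design;
permutation-null calibration over 200 simulated networks. The 10x5 CV
protocol remains the package default for real analyses.

## Known limitations

* Dense N x d intermediates mean memory grows with the gene universe;
  desk-scale and mid-scale collections are fine, genome-scale runs with
  tens of thousands of sets would want sparse blocked updates.
* No gene-identifier mapping: symbols are matched verbatim, so inputs
  must share a namespace.
* The model predicts association, not causation, and inherits every bias
  of the gene-set collections it is trained on; hub genes present in
  many sets receive more messages by construction.
* The loss is plain unweighted cross-entropy. The class imbalance of
  realistic label sets (roughly 1:7) is instead mitigated where it
  matters — by sampling the negative set rather than using every
  non-risk gene — and AUPRC is reported alongside AUROC because it is
  the imbalance-sensitive metric.
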