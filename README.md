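# hyperAD

Disease risk gene prioritization on gene-set hypergraphs.

## What problem this solves, and for whom

Computational gene prioritization usually propagates risk over pairwise
gene networks (PPI, co-expression), which cannot represent the
multi-gene functional modules that drive complex polygenic diseases.
hyperAD is for computational geneticists and systems biologists who have
(a) annotated gene-set collections in GMT format (e.g. MSigDB H/C1–C8),
(b) a curated list of known risk genes, and (c) a pool of presumed
non-risk genes — and who want a genome-wide ranking of candidate risk
genes that exploits the *higher-order* co-membership structure of those
collections.

## The model

Genes are nodes and gene sets are hyperedges of a hypergraph with binary
incidence **H** (N×M), node degree d(v) = Σₑ w(e) H(v,e), hyperedge
degree δ(e) = Σᵥ H(v,e). One-hot gene inputs are embedded
(x⁽⁰⁾ = ReLU(xΘ₀ + b₀), realized as a table lookup) and refined by
stacked two-stage message-passing blocks:

* node → hyperedge: yₑ = ReLU( Σ_{v∈e} (x_v / d(v)) Θ_{v→e} )
* hyperedge → node: x_v′ = ReLU( Σ_{e∋v} w(e) · yₑ Θ_{e→v} + x_v )

with the disease-specific hyperedge weight
**w(e) = |e ∩ V_d| / δ(e)** — the fraction of the gene set's members
that are known risk genes — so that disease-relevant biological contexts
dominate the aggregation. A softmax head Z = softmax(x Θ₁ + b₁) gives a
per-gene risk score; training is transductive cross-entropy over the
labeled genes only, optimized with Adam (hand-written backprop, verified
against numerical differentiation). The package also provides the
normalized hypergraph Laplacian Δ = I − D_v^{−1/2} H W D_e^{−1} Hᵀ
D_v^{−1/2} and the classical one-shot hypergraph convolution layer as a
baseline, repeated stratified cross-validation (AUROC/AUPRC), and three
downstream validation statistics: first-decile hypergeometric enrichment,
permutation tests of network association with known genes, and Kendall
tau-b monotone trend tests across ordinal disease stages with
Benjamini–Hochberg FDR control. Seeded generators produce planted
hypergraphs, staged expression matrices and toy networks so the whole
pipeline runs without external downloads.

## Worked example

```r
library(hyperAD)

## a 300-gene hypergraph with a planted 30-gene disease module; half of
## the module is exposed as training positives, half is held out
sim <- generatePlantedHypergraph(plantedHypergraphSpec(seed = 1))
sim$hypergraph
#> Hypergraph: 299 genes x 160 hyperedges, 2352 incidences
#> collections: relevant, background

fit <- trainHyperAD(sim$hypergraph, sim$labels, hyperADConfig(seed = 1))
fit
#> HyperADFit: 299 genes, 2 block(s), embedDim 128, weightMode 'ad_weighted'
#> training loss 0.6919 -> 0.0029 over 200 epochs

## genome-wide ranking, known positives excluded
ranking <- prioritizeGenes(riskScores(fit), exclude = sim$labels@positives)
head(ranking, 10)
#> [1] "G0044" "G0160" "G0217" "G0172" "G0198" "G0187" "G0014" "G0263"
#> [9] "G0020" "G0248"

length(intersect(ranking[1:15], sim$heldoutPositives))
#> [1] 14
```

The training loss falls from 0.69 (chance) to ~0.003, and 14 of the 15
held-out disease genes land in the top 15 of the ranking — the model
recovers the planted module from hyperedge co-membership alone. The same
pipeline runs from the shell via the `inst/scripts/hyperad` entry point
(`hyperad simulate|build|train|cv|validate`), which writes TSV tables
plus a JSON run summary recording the seed.

Real data enter through the same interfaces: `readGMT()` for gene-set
collections, one-symbol-per-line gene lists for positives/negative
pools, two-column TSV edge lists for networks, and a genes × samples TSV
plus ordinal stage vector for expression trend testing.

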