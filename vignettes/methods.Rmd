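---
title: "Methods: from raw counts to communication networks and drug ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw counts to communication networks and drug ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterCellDR)
```

InterCellDR chains five stages: preprocessing, cluster annotation,
differential expression, communication-network discovery, and drug
ranking. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions that make results
reproducible bit-for-bit, and what the synthetic test corpus does and
does not establish about real data.

## Preprocessing

**Quality control.** Cells are kept when their detected gene count
(counts > 0) lies in `[min_genes, max_genes]` (defaults 200 and 7500) and
their mitochondrial count fraction is at most `max_mito_frac` (default
10%). Mitochondrial genes are recognized by a configurable symbol prefix
(default `"MT-"`); no fixed gene list is assumed. The filter is idempotent
and never touches the gene axis. Mouse data are mapped to human symbols by
a user-supplied two-column ortholog table before analysis; genes absent
from the table are dropped, and several mouse genes mapping to one human
symbol are *summed*, so each cell's library-size contribution survives the
mapping.

**Normalization.** We compute analytic Pearson residuals under a
negative-binomial count model with a sequencing-depth offset: gene *g*'s
expected count in cell *j* is `mu_gj = p_g * depth_j`, where `p_g` is the
gene's share of all counts, and the residual is
`(x − mu) / sqrt(mu + mu²/θ)` with θ = 100. For a gene that only tracks
depth, residual variance is ≈ 1, so biological structure appears as excess
variance. Residuals are clipped to `±sqrt(n_cells)` (a cell count's worth
of standard errors caps any single cell's influence) and all-zero genes
map to all-zero rows. The assumption is that sequencing depth is the only
technical covariate; batch effects are out of scope.

**Imputation** is off by default. When requested, the matrix is
reconstructed from its top-k singular components; since the input is
nonnegative, negative reconstructed values can only be error, so each
gene's negative values calibrate a magnitude threshold below which
reconstructed entries are reset to zero (the `error_quantile` of those
magnitudes, default the largest), and residual negatives are clamped. The
rank is user-set or chosen at the largest gap in the top-100 singular
values.

**Embedding and clustering.** The top `n` genes by residual variance
(default 3000; ties broken by gene symbol) feed a centered PCA. Component
signs are fixed by making each component's largest-magnitude loading
positive, so the embedding is fully deterministic. Clustering builds a
k-nearest-neighbor graph (default k = 20, a common neighborhood size at
this cell-count scale; the parameter is exposed rather than fixed), weights
edges by the Jaccard overlap of neighborhoods, prunes weights below 1/15,
and runs Louvain at a resolution in [0.1, 2]. Cluster ids are relabeled
0..K−1 by decreasing size with ties broken by the smallest member barcode.
UMAP (via `uwot`, single-threaded) is reproducible under a fixed seed; all
stochastic stages take explicit seeds and default to 0.

## Cluster annotation

For cluster *N*, genes are ranked by mean expression in *N* minus mean
expression elsewhere, on normalized values (a switch to imputed values
exists but normalized is the default — enrichment on smoothed values can
only blur the ranking). Rank ties break by gene symbol. Each candidate
cell type's marker set is scored with the weighted Kolmogorov–Smirnov
running sum: walking the ranking, hits add `|r|^p / Σ_hits |r|^p`, misses
subtract `1/(N − N_hits)`; the score is the signed maximum excursion,
always in [−1, 1]. The weight exponent defaults to p = 1 (the standard
weighted statistic) and is exposed. Scores are compared raw — no
permutation normalization — because the annotation rule is an argmax over
candidates on a single shared ranking, and rawness keeps it deterministic.
A cluster is labeled `Unknown` when no candidate scores above zero;
manual corrections are tracked by provenance and survive re-annotation
unless forced.

One numerical convention matters: when the maximum positive and maximum
negative excursions tie in magnitude exactly, the positive one wins (with
a 1e-9 float guard). Ties of this kind only arise for the unweighted
statistic, whose step sizes are rational.

## Differential expression

Two tests run per gene between test and control cells of one cell type:
the Wilcoxon rank-sum test (`stats::wilcox.test`, exact for small untied
samples) and a bimodal likelihood-ratio test in which each group is a
mixture of a point mass at zero and a Gaussian over nonzero values.
Parameters are at their maximum-likelihood values with an n-denominator
variance floored at 1e-6 — the floor guards groups with fewer than two
distinct nonzero values, and MLE fitting makes the statistic
`2(ll_x + ll_y − ll_pooled)` nonnegative by nesting. Three parameters
(mixing weight, mean, variance) are freed per group, so the reference
distribution is chi-square with 3 degrees of freedom; an all-zero pooled
input returns p = 1 by convention. Both p-value vectors are adjusted
separately (Bonferroni by default, mirroring the convention of the
wrapped single-cell toolkits), and a gene is *up* only when
`logFC > fc_threshold` (default 0.08) and both adjusted p-values are
below `p_threshold` (default 0.05).

Gene-set enrichment of the up genes uses the one-sided Fisher exact test
(the hypergeometric tail), Benjamini–Hochberg adjusted, with the default
universe being all genes in the matrix after QC. Flat term→gene sets are
consumed as GMT; ontology-graph propagation is deliberately out of scope.

## Communication networks

Ligand and receptor tiers come straight from the DE table: *up* means the
full dual-test criterion, *expressed* means `logFC > 0`, so up ⊆
expressed. Intersecting tiers with the ligand–receptor database yields
four upstream networks (up→expressed, expressed→up, up→up, combined =
their union). All downstream scoring uses the *receiver* cell type's fold
changes — downstream signaling happens inside the receiver — and any gene
missing from the DE table scores fc = 0, so unmeasured genes neither help
nor hurt a path.

**Curated (KEGG-like) graphs.** Per-pathway edge lists are merged on gene
symbol into one directed graph, so crosstalk between pathways survives;
"target genes" are nodes with out-degree 0 *in the merged graph*. For
every receptor–target pair the unweighted shortest path is found
breadth-first; among equally short paths the lexicographically smallest
node sequence wins, making output independent of edge-list order. A path
is kept when its mean fold change exceeds the score threshold (default
0.1).

**Dense (STRING-like) graphs.** Exhaustive receptor→sink search is
meaningless on a dense interactome, so discovery is greedy: starting from
the receptor, the `k1` highest-|fc| genes not yet in the network are
candidates (default 10); minimum-weight paths (edge weight
`1/max(|fc_i|, ε) + 1/max(|fc_j|, ε)`, ε = 1e-6 so zero-fold-change genes
make edges effectively impassable) run from every current network node to
every candidate; paths longer than `k2` nodes (default 5) are discarded;
the best survivor by (score, then fewer nodes, then lexicographic
sequence) is added; iteration stops at `N` network nodes (default 50) or
when no admissible path remains — so the final network can overshoot `N`
by at most `k2 − 1` nodes, and growth stops rather than trimming the last
path. Candidates are ranked by |fc| alone, with no significance filter.
The published weight formula is typographically garbled; the
sum-of-reciprocals reading is used because it is the only one that makes
high-fold-change genes cheap to route through, which is what the greedy
objective needs.

The assembled communication network merges ligand→receptor edges with
each receptor's downstream network, flags transcription factors from the
TF–target table, and annotates every node with its fold change.

## Drug ranking and clustering

The drug rank matrix has one column per drug, each a permutation of
1..n_genes (rank 1 = most up-regulated; replicate signature columns are
averaged before ranking, ties broken by gene symbol, and columns are
validated as permutations on load). The network's up-regulated genes are
scored against each drug's ranking with the *unweighted* (p = 0) running
sum — the rank matrix carries no magnitudes to weight by — and the K
lowest (most negative) scores are reported: a drug that pushes the
signature to the bottom of its ranking is a candidate reverser. Discovery
uses the up set alone; the cross-GSEA *similarity* between drugs combines
directions, `S[i,j] = ES_up(i→j) − ES_down(i→j)` over each drug's top-150
up and down genes, the standard reversal-score convention that makes
self-similarity maximal (an up-only strategy flag exists).

Affinity propagation clusters the (symmetrized) similarity matrix with
the shared preference set to the median off-diagonal similarity, damping
0.5, up to 1000 sweeps, convergence declared after 50 sweeps of stable
exemplars, and a single damping-0.9 retry on non-convergence. Message
passing on exactly symmetric inputs oscillates, so a deterministic jitter
(1e-9 of the similarity span, fixed internal seed) breaks ties; an input
with *no* structure at all (all equal similarities) short-circuits to one
cluster. Chemical clustering computes Tanimoto similarity
`c/(a + b − c)` over 1024-bit hashed linear-path fingerprints (OpenBabel
FP2 via ChemmineOB; any fingerprinter with bit-set semantics can
substitute), with two empty fingerprints defined as identical.

## The synthetic corpus

`fixture_spec()` freezes the reference study conditions: four cell types
with disjoint 10-gene marker blocks (8× elevated in their own type), one
marker-free noise population, 240 cells per population (≈120 per condition
— enough for the Bonferroni-adjusted dual test to be well powered for the
planted effects, and in line with per-type cell counts in typical
cohorts), 500 genes including five `MT-` genes, negative-binomial counts
with dispersion 0.5, log-normal depth (mean 2000, sdlog 0.3), and 20%
extra dropout. Test-group cells carry a planted fold change of 1
natural-log unit on the genes wired into the ligand–receptor pairs and
the background graphs; the drug fixture plants one reverser whose column
ranks those genes in the bottom decile. All generators are pure functions
of the spec's seed.

The corpus emulates depth variation, overdispersion, dropout, marker
structure and condition effects. It does **not** emulate batch effects,
doublets, ambient RNA, realistic pathway topology, or the moderated
z-score distributions of real perturbation atlases — so passing tests
demonstrate algorithmic correctness and stability under the stated noise
model, not biological validity on any particular cohort.

Problem sizes throughout the tests and the acceptance script (500–1000
genes, ~1200 cells, ≤12-node oracle graphs, 50 drugs) were chosen so that
exhaustive oracles — full path enumeration, rank-split enumeration for the
Wilcoxon test, hypergeometric tail sums — remain feasible alongside the
pipeline.

## Known limitations

- The ligand–receptor, TF–target, signaling-graph and drug tables are
  consumed in declared formats; curating them is the user's job, and no
  live database access is attempted.
- Annotation is per-cluster; per-cell label transfer is out of scope.
- The greedy dense-graph search is order-deterministic but, like any
  greedy method, not globally optimal; its guarantees are the bounds
  `path length ≤ k2` and `network size < N + k2`.
- Statistical significance of individual ligand–receptor pairs (e.g. by
  permutation) is not computed; tiering is threshold-based by design.
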