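# InterCellDR

InterCellDR is an R toolkit for asking, from raw single-cell RNA-seq
counts, three questions about a diseased tissue microenvironment:

1. **Who is there?** — cluster cells and annotate each cluster with a cell
   type by marker-gene enrichment.
2. **How do they talk?** — between two experimental conditions (e.g.
   disease vs. control), find up-regulated ligands in a *sender* cell type,
   up-regulated receptors in a *receiver* cell type, and the downstream
   signaling cascades those receptors activate.
3. **What might silence the conversation?** — rank drugs whose
   perturbation signatures *reverse* the network's up-regulated genes, and
   group the top candidates by signature similarity and by chemical
   structure.

It is aimed at computational biologists who want a scriptable,
deterministic version of this style of microenvironment analysis, with
every stage testable offline against synthetic data with planted ground
truth.

## The models at the core

**Cell-type annotation.** For cluster *N*, genes are ranked by
`logFC_g = mean_g(cluster N) − mean_g(other cells)` on variance-stabilized
expression. Each candidate type's marker set is scored on this ranking with
the weighted Kolmogorov–Smirnov running-sum enrichment score ES ∈ [−1, 1]
(hits add `|r_g|^p / Σ_hits |r|^p`, misses subtract `1/(N − N_hits)`; ES is
the signed maximum excursion). The argmax candidate wins if its ES is
positive; otherwise the cluster is `Unknown`.

**Differential expression.** Within a cell type, test vs. control cells
are compared per gene by (i) the Wilcoxon rank-sum test and (ii) a bimodal
likelihood-ratio test (point mass at zero + Gaussian over nonzero values).
A gene is *up* when `logFC > 0.08` and both Bonferroni-adjusted p-values
are `< 0.05` (thresholds configurable).

**Communication networks.** Up/expressed ligand and receptor tiers are
intersected with a ligand–receptor database to form four upstream networks
(up→expressed, expressed→up, up→up, combined). Downstream of each
receptor:

- *curated (KEGG-like) graphs*: every shortest path from receptor to a
  sink gene (out-degree 0) is scored `s = mean fc(path nodes)` and kept if
  `s` exceeds a threshold;
- *dense (STRING-like) graphs*: a greedy search repeatedly adds the
  best-scoring minimum-weight path (edge weight
  `1/|fc_i| + 1/|fc_j|`) from the current network to one of the `k1`
  highest-|fc| candidate genes, discarding paths longer than `k2` nodes,
  until the network reaches `N` nodes.

**Drug ranking.** Against a connectivity-map style rank matrix (each drug
column a permutation of genes, rank 1 = most up-regulated), the network's
up-regulated genes are scored with the unweighted ES per drug; the most
negative scores mark signature reversers. Top drugs are clustered by
cross-GSEA similarity (`S[i,j] = ES_up(i→j) − ES_down(i→j)`) with affinity
propagation, and by Tanimoto similarity `c/(a+b−c)` of 1024-bit hashed-path
chemical fingerprints.

## Worked example

The package ships generators for a complete synthetic corpus — counts with
four planted cell types plus a marker-free noise population, a
ligand–receptor table, background signaling graphs, and a drug rank matrix
with one planted reverser — so the whole pipeline runs in seconds:

```r
library(InterCellDR)
spec <- fixture_spec(seed = 0)
res  <- run_pipeline(spec)

res$annotation[, c("cluster", "label", "best_es")]
#>   cluster     label    best_es
#> 1       0   Unknown -0.9387755
#> 2       1 CellTypeA  1.0000000
#> 3       2 CellTypeC  1.0000000
#> 4       3 CellTypeD  1.0000000
#> 5       4 CellTypeB  1.0000000

res$upstream
#> upstream ligand-receptor networks:
#>   up_exp   6 edges
#>   exp_up   9 edges
#>   up_up    6 edges
#>   combined 9 edges

res$network
#> communication network CellTypeA -> CellTypeB: 20 nodes (3 ligands,
#> 3 receptors, 4 TFs), 28 edges

head(res$drug_scores, 5)
#>     drug         es rank
#> 1 drug01 -0.9278351    1
#> 2 drug34 -0.2859107    2
#> 3 drug09 -0.2680412    3
#> 4 drug03 -0.2584192    4
#> 5 drug23 -0.2570447    5
```

Every planted cluster is labeled correctly and the noise cluster (all
marker ESs negative) is `Unknown`. The upstream networks connect the three
planted ligands to the three planted receptors; the communication network
adds the downstream cascade with transcription-factor flags and per-node
fold changes. `drug01` — the planted reverser, whose column pushes the
planted up-regulated genes to the bottom decile of its ranking — wins with
ES −0.93, far below the scattered-signature drugs near −0.3.

A thin CLI over the same functions lives in `inst/cli/intercelldr.R`
(subcommands `fixtures`, `preprocess`, `annotate`, `de`, `drugs`).

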