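# End-to-end driver: fixtures (or user files) -> preprocess -> annotate ->
# differential expression -> communication networks -> drug ranking.

#' Run the full analysis pipeline on a fixture corpus
#'
#' Generates the synthetic corpus for `spec`, then runs QC, normalization,
#' variable-gene selection, PCA, clustering, marker-based annotation,
#' test-vs-control differential expression within the sender and receiver
#' cell types, upstream ligand-receptor networks, downstream signaling
#' discovery on both background graphs, communication-network assembly,
#' and signature-reversal drug ranking.
#'
#' @param spec `fixture_spec` describing the corpus.
#' @param sender,receiver cell-type labels for the communication contrast
#'   (defaults: first and second planted types).
#' @param fc_threshold,p_threshold DE thresholds (defaults 0.08 / 0.05).
#' @param resolution clustering resolution.
#' @param k_neighbors clustering neighborhood size.
#' @param n_hvg variable genes for the embedding.
#' @param n_pcs principal components.
#' @param score_threshold KEGG-mode path score threshold.
#' @param k1,k2,N STRING-mode search width, depth and node limit.
#' @param top_k drugs to keep in the reversal ranking.
#' @param seed seed for the stochastic stages (clustering).
#' @param drop_cells optional fraction of cells removed uniformly at
#'   random before analysis (robustness experiments).
#' @return list with every intermediate product (counts, normalized
#'   matrix, clusters, annotation, DE tables, upstream networks,
#'   downstream networks, `comm_network`, drug scores).
#' @export
run_pipeline <- function(spec = fixture_spec(),
                         sender = spec$cell_types[1],
                         receiver = spec$cell_types[2],
                         fc_threshold = 0.08, p_threshold = 0.05,
                         resolution = 0.5, k_neighbors = 20,
                         n_hvg = 200, n_pcs = 30,
                         score_threshold = 0.1, k1 = 10, k2 = 5, N = 50,
                         top_k = 30, seed = 0, drop_cells = 0) {
  fx <- make_counts(spec)
  counts <- fx$counts
  if (drop_cells > 0) {
    keep <- with_seed(seed + 17, {
      n <- ncol(counts)
      sort(sample.int(n, ceiling((1 - drop_cells) * n)))
    })
    counts <- counts[, keep, drop = FALSE]
  }
  counts <- qc_filter(counts, min_genes = 50, max_genes = nrow(counts),
                      max_mito_frac = 0.25)
  norm <- normalize_expr(counts)
  hvg <- select_hvg(norm, min(n_hvg, nrow(norm)))
  pca <- embed_pca(norm, hvg, n_pcs = n_pcs)
  cl <- cluster_cells(pca, k_neighbors = k_neighbors,
                      resolution = resolution, seed = seed)
  ann <- annotate_clusters(norm, cl, fx$markers)
  label_of <- ann$label[match(cl, ann$cluster)]
  names(label_of) <- names(cl)
  design <- fx$design[fx$design$cell %in% colnames(counts), ]
  de_for <- function(type) {
    cells <- names(label_of)[label_of == type]
    grp <- design$group[match(cells, design$cell)]
    de_test(norm, cells[grp == "test"], cells[grp == "control"],
            fc_threshold, p_threshold)
  }
  sender_de <- de_for(sender)
  receiver_de <- de_for(receiver)
  db <- make_lr_db(spec)
  up <- upstream_networks(sender_de, receiver_de, db)
  fc <- fc_map(receiver_de)
  graphs <- make_graphs(spec)
  receptors <- unique(up$combined$receptor)
  down_kegg <- kegg_downstream(receptors, fc, graphs$kegg, score_threshold)
  down_string <- string_downstream(receptors, fc, graphs$string,
                                   k1 = k1, k2 = k2, N = N)
  tf <- make_tf_table(spec)
  net <- build_comm_network(sender, receiver, up, down_kegg, tf, fc)
  up_genes <- unique(c(net$nodes$gene[net$nodes$fc > fc_threshold]))
  drug_fx <- make_drug_fixture(spec)
  drugs <- signature_drug_discovery(up_genes, drug_fx$rank_matrix,
                                    K = top_k)
  targeted <- drugs_by_target(net$nodes$gene, drug_fx$targets)
  list(spec = spec, counts = counts, normalized = norm, clusters = cl,
       annotation = ann, cell_labels = label_of, design = design,
       sender_de = sender_de, receiver_de = receiver_de,
       upstream = up, downstream_kegg = down_kegg,
       downstream_string = down_string, network = net,
       drug_scores = drugs, drug_targets = targeted,
       drug_fixture = drug_fx)
}

#' Node set of a communication analysis
#'
#' Upstream ligand/receptor genes plus downstream nodes — the gene set
#' compared in robustness and threshold-nesting experiments.
#'
#' @param res result of [run_pipeline()].
#' @return character vector of gene symbols.
#' @export
pipeline_network_genes <- function(res) {
  unique(c(res$upstream$combined$ligand, res$upstream$combined$receptor,
           res$downstream_kegg$nodes, res$downstream_string$nodes))
}
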