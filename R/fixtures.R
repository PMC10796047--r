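# Deterministic generators for every input the pipeline consumes, with
# planted ground truth: typed cell populations with marker genes, planted
# test-vs-control fold changes wired into ligand-receptor pairs and
# background signaling graphs, and a drug fixture with one planted
# signature reverser. All generators are pure functions of the spec.

#' Specification for the synthetic fixture corpus
#'
#' The defaults define the reference study conditions used throughout the
#' test suite: four planted cell types with disjoint 10-gene marker
#' blocks plus one marker-free noise population, negative-binomial counts
#' (dispersion 0.5) with log-normally varying sequencing depth and 20%
#' extra dropout, and test-group fold changes of 1 natural-log unit
#' planted on the genes that feed the ligand-receptor pairs and signaling
#' graphs.
#'
#' @param seed RNG seed (mandatory for reproducibility; default 0).
#' @param n_cell_types planted cell types (default 4).
#' @param markers_per_type marker genes per type (default 10).
#' @param cells_per_type cells per type and per noise population
#'   (default 240, i.e. about 120 cells per condition within a type).
#' @param n_genes total genes including markers and 5 mitochondrial
#'   genes (default 500).
#' @param depth_mean mean sequencing depth per cell (default 2000).
#' @param depth_sdlog log-sd of the depth distribution (default 0.3).
#' @param dropout extra zero-inflation probability (default 0.2).
#' @param nb_dispersion negative-binomial dispersion (default 0.5).
#' @param marker_fold expression multiplier of a marker in its own type
#'   (default 8).
#' @param de_lfc planted natural-log fold change in test-group cells
#'   (default 1).
#' @param include_noise add a marker-free noise population (default TRUE).
#' @param n_drugs drug fixture size (default 50).
#' @param string_extra extra non-DE nodes in the dense graph (default 12).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 0, n_cell_types = 4, markers_per_type = 10,
                         cells_per_type = 240, n_genes = 500,
                         depth_mean = 2000, depth_sdlog = 0.3,
                         dropout = 0.2, nb_dispersion = 0.5,
                         marker_fold = 8, de_lfc = 1,
                         include_noise = TRUE, n_drugs = 50,
                         string_extra = 12) {
  stopifnot(n_cell_types >= 2, markers_per_type >= 1, cells_per_type >= 10,
            n_genes >= n_cell_types * markers_per_type + 60,
            depth_mean > 0, dropout >= 0, dropout < 1, nb_dispersion > 0)
  spec <- as.list(environment())
  spec$genes <- c(sprintf("GENE%03d", seq_len(n_genes - 5)),
                  paste0("MT-G", 1:5))
  spec$cell_types <- paste0("CellType", LETTERS[seq_len(n_cell_types)])
  mk <- matrix(spec$genes[seq_len(n_cell_types * markers_per_type)],
               nrow = markers_per_type)
  spec$markers <- data.frame(
    cell_type = rep(spec$cell_types, each = markers_per_type),
    gene = as.vector(mk), stringsAsFactors = FALSE)
  # network gene roles, planted after the marker block
  base <- n_cell_types * markers_per_type
  take <- function(from, n) spec$genes[base + from + seq_len(n) - 1]
  spec$ligands <- take(1, 3)
  spec$receptors <- take(4, 3)
  spec$intermediates <- take(7, 12)
  spec$sinks <- take(19, 6)
  spec$extra_lr <- take(25, 4) # ligands/receptors left out of the DE set
  spec$de_genes <- stats::setNames(
    rep(de_lfc, 3 + 3 + 8 + 3),
    c(spec$ligands, spec$receptors, spec$intermediates[1:8],
      spec$sinks[1:3]))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate counts, design and ground truth
#'
#' Negative-binomial gene-by-cell counts with per-type elevated marker
#' means and planted test-group shifts, plus a design table (two samples
#' per group) and the true cell-type labels and DE genes.
#'
#' @param spec `fixture_spec`.
#' @return list: `counts` (genes x cells), `design` (cell, sample,
#'   group), `true_types` (named by barcode), `de_genes` (named lfc
#'   vector), `markers`.
#' @export
make_counts <- function(spec) {
  with_seed(spec$seed, {
    types <- spec$cell_types
    if (spec$include_noise) types <- c(types, "Noise")
    n_cells <- length(types) * spec$cells_per_type
    barcodes <- sprintf("CELL%04d", seq_len(n_cells))
    true_types <- rep(types, each = spec$cells_per_type)
    names(true_types) <- barcodes
    group <- rep(rep(c("control", "test"), length.out = spec$cells_per_type),
                 length(types))
    sample_id <- paste0(group, "_s",
                        1 + (seq_len(n_cells) %% 2))
    design <- data.frame(cell = barcodes, sample = sample_id, group = group,
                         stringsAsFactors = FALSE)
    base_w <- stats::rlnorm(length(spec$genes), meanlog = 0, sdlog = 0.5)
    names(base_w) <- spec$genes
    depth <- stats::rlnorm(n_cells, log(spec$depth_mean), spec$depth_sdlog)
    counts <- matrix(0L, length(spec$genes), n_cells,
                     dimnames = list(spec$genes, barcodes))
    size <- 1 / spec$nb_dispersion
    for (j in seq_len(n_cells)) {
      w <- base_w
      ty <- true_types[j]
      if (ty != "Noise") {
        mg <- spec$markers$gene[spec$markers$cell_type == ty]
        w[mg] <- w[mg] * spec$marker_fold
      }
      if (group[j] == "test")
        w[names(spec$de_genes)] <- w[names(spec$de_genes)] *
          exp(spec$de_genes)
      mu <- depth[j] * w / sum(w)
      x <- stats::rnbinom(length(mu), mu = mu, size = size)
      if (spec$dropout > 0)
        x <- x * stats::rbinom(length(x), 1, 1 - spec$dropout)
      counts[, j] <- x
    }
    list(counts = counts, design = design, true_types = true_types,
         de_genes = spec$de_genes, markers = spec$markers)
  })
}

#' Generate the ligand-receptor database fixture
#'
#' Wires the planted sender ligands to the planted receiver receptors
#' (all pairs), adds pairs involving the non-DE extra ligands/receptors,
#' and a few decoy pairs over genes absent from the expression fixture.
#'
#' @param spec `fixture_spec`.
#' @return `lr_db` object.
#' @export
make_lr_db <- function(spec) {
  lig <- c(rep(spec$ligands, each = length(spec$receptors)),
           spec$extra_lr[1:2], "DECOYL1")
  rec <- c(rep(spec$receptors, times = length(spec$ligands)),
           spec$extra_lr[3:4], "DECOYR1")
  lr_db(lig, rec)
}

#' Generate background signaling graphs
#'
#' KEGG-like: a layered DAG receptor -> intermediates -> sinks (sinks have
#' out-degree 0). STRING-like: the same nodes plus extra genes with denser
#' random directed edges, receptors guaranteed connected.
#'
#' @param spec `fixture_spec`.
#' @return list `kegg` and `string`, both `signaling_graph`.
#' @export
make_graphs <- function(spec) {
  with_seed(spec$seed + 1, {
    layers <- list(spec$receptors,
                   spec$intermediates[1:6],
                   spec$intermediates[7:12],
                   spec$sinks)
    edges <- NULL
    for (l in seq_len(length(layers) - 1)) {
      for (v in layers[[l]]) {
        nxt <- sample(layers[[l + 1]], min(2, length(layers[[l + 1]])))
        edges <- rbind(edges, data.frame(from = v, to = nxt,
                                         stringsAsFactors = FALSE))
      }
    }
    kegg <- signaling_graph(edges, "kegg-like")
    extra <- sprintf("SGENE%02d", seq_len(spec$string_extra))
    nodes <- c(spec$receptors, spec$intermediates, spec$sinks, extra)
    n <- length(nodes)
    am <- matrix(stats::runif(n * n) < 0.12, n, n)
    diag(am) <- FALSE
    se <- data.frame(from = nodes[row(am)[am]], to = nodes[col(am)[am]],
                     stringsAsFactors = FALSE)
    # every receptor keeps at least one outgoing edge
    for (r in spec$receptors)
      se <- rbind(se, data.frame(from = r,
                                 to = sample(spec$intermediates, 2),
                                 stringsAsFactors = FALSE))
    string <- signaling_graph(rbind(se, edges), "string-like")
    list(kegg = kegg, string = string)
  })
}

#' Generate the transcription-factor/target table fixture
#' @param spec `fixture_spec`.
#' @return data.frame (tf, target); TFs are drawn from the deep
#'   intermediates and sinks.
#' @export
make_tf_table <- function(spec) {
  tfs <- c(spec$intermediates[7:9], spec$sinks[1])
  data.frame(tf = rep(tfs, each = 2),
             target = rep(spec$sinks[2:3], times = length(tfs)),
             stringsAsFactors = FALSE)
}

#' Generate the drug fixture
#'
#' A genes x drugs rank matrix of random permutations with one planted
#' reverser whose column pushes the signature genes into the bottom
#' decile; a drug-target table; and a SMILES table containing an alkane
#' family and an aromatic family for structure clustering.
#'
#' @param spec `fixture_spec`.
#' @param signature_genes genes the reverser suppresses (default: the
#'   planted DE genes).
#' @return list: `rank_matrix`, `reverser` (drug id), `targets` (named
#'   list), `smiles` (named character).
#' @export
make_drug_fixture <- function(spec, signature_genes = names(spec$de_genes)) {
  with_seed(spec$seed + 2, {
    genes <- spec$genes
    n <- length(genes)
    drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
    reverser <- drugs[1]
    m <- matrix(0L, n, spec$n_drugs, dimnames = list(genes, drugs))
    for (d in seq_len(spec$n_drugs)) m[, d] <- sample.int(n)
    sig <- intersect(signature_genes, genes)
    decile <- max(floor(n / 10), length(sig))
    bottom <- sample((n - decile + 1):n, length(sig))
    rest <- sample(setdiff(seq_len(n), bottom))
    m[sig, 1] <- bottom
    m[setdiff(genes, sig), 1] <- rest
    validate_rank_matrix(m)
    targets <- lapply(seq_along(drugs), function(i)
      sample(c(names(spec$de_genes), spec$extra_lr), sample(1:3, 1)))
    names(targets) <- drugs
    alkanes <- c("CCCCCC", "CCCCCCC", "CCCCCCCC")
    aromatics <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1")
    smiles <- stats::setNames(c(alkanes, aromatics), drugs[1:6])
    list(rank_matrix = m, reverser = reverser, targets = targets,
         smiles = smiles)
  })
}

#' Write the whole fixture corpus to a directory
#'
#' Emits every generated object in the standard plain-text formats of the
#' I/O layer, so the full pipeline can run offline from files.
#'
#' @param spec `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cx <- make_counts(spec)
  write_counts(cx$counts, file.path(dir, "counts.mtx"))
  write_design(cx$design, file.path(dir, "design.tsv"))
  write_marker_table(cx$markers, file.path(dir, "markers.tsv"))
  write_lr_table(make_lr_db(spec), file.path(dir, "lr.tsv"))
  gs <- make_graphs(spec)
  write_signaling_graph(gs$kegg, file.path(dir, "kegg_edges.tsv"))
  write_signaling_graph(gs$string, file.path(dir, "string_edges.tsv"))
  write_tf_table(make_tf_table(spec), file.path(dir, "tf.tsv"))
  dx <- make_drug_fixture(spec)
  write_drug_rank_matrix(dx$rank_matrix, file.path(dir, "drug_ranks.tsv"))
  write_drug_targets(list(targets = dx$targets, smiles = dx$smiles),
                     file.path(dir, "drug_targets.tsv"))
  invisible(dir)
}
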