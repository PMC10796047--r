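# GSEA-based cell-type assignment of clusters against a marker-gene table,
# manual correction, per-group cell-type distributions, and EMT/PRO scores.

#' Cluster-versus-rest log fold change ranking
#'
#' For every gene, mean normalized expression in the cluster minus the
#' mean over all other cells. The ranking is sorted decreasing; ties are
#' broken by gene symbol so it is reproducible bit-for-bit.
#'
#' @param e normalized genes x cells matrix.
#' @param cl named integer cluster assignment.
#' @param cluster_id cluster to rank (must be non-empty and not all cells).
#' @return named numeric vector, decreasing, covering all genes.
#' @export
cluster_logfc <- function(e, cl, cluster_id) {
  x <- as_dense(e)[, names(cl), drop = FALSE]
  inside <- cl == cluster_id
  if (!any(inside)) stop("cluster ", cluster_id, " is empty")
  if (all(inside)) stop("cluster ", cluster_id,
                        " contains every cell; no contrast possible")
  r <- rowMeans(x[, inside, drop = FALSE]) -
    rowMeans(x[, !inside, drop = FALSE])
  r[order(-r, names(r))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranking from top to bottom; genes in the set (hits) push the
#' running sum up by `|r|^p / sum_hits |r|^p`, misses pull it down by
#' `1 / (N - N_hits)`. The score is the signed maximum deviation from
#' zero, always in `[-1, 1]`. With `weight_exponent = 0` all hits weigh
#' equally (classic unweighted KS statistic).
#'
#' @param ranking named numeric vector, sorted decreasing (a ranked gene
#'   list, e.g. from [cluster_logfc()]).
#' @param gene_set character vector of gene symbols.
#' @param weight_exponent hit-weight exponent p (default 1).
#' @return enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranking, gene_set, weight_exponent = 1) {
  n <- length(ranking)
  hit <- names(ranking) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranking")
  if (nh == n) stop("gene set covers the whole ranking; no misses to walk")
  w <- abs(ranking)^weight_exponent
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { # degenerate all-zero hit statistics: fall back to equal
    w[hit] <- 1
    tot <- nh
  }
  step <- ifelse(hit, w / tot, -1 / (n - nh))
  run <- cumsum(step)
  mx <- max(run)
  mn <- min(run)
  # signed maximum deviation; an exact +/- tie resolves to the positive
  # extreme (tolerance guards float noise in the running sum)
  if (abs(mx) >= abs(mn) - 1e-9) mx else mn
}

#' Annotate clusters by marker-set enrichment
#'
#' For each cluster, ranks genes by cluster-versus-rest log fold change
#' and scores every candidate cell type's marker set with [gsea_es()].
#' The top-scoring candidate wins if its score is positive; otherwise the
#' cluster is labeled `"Unknown"`. Ties go to the candidate listed first
#' in the marker table.
#'
#' @param e normalized genes x cells matrix.
#' @param cl named integer cluster assignment.
#' @param markers data.frame (cell_type, gene).
#' @param candidates candidate cell types (default: marker-table order).
#' @param weight_exponent GSEA hit-weight exponent (default 1).
#' @param prior optional previous annotation whose manually corrected rows
#'   are preserved unless `force = TRUE`.
#' @param force re-annotate even manually corrected clusters.
#' @return data.frame of class `cluster_annotation` (cluster, label,
#'   best_es, provenance) with the full score matrix in attribute
#'   `scores`.
#' @export
annotate_clusters <- function(e, cl, markers, candidates = NULL,
                              weight_exponent = 1, prior = NULL,
                              force = FALSE) {
  candidates <- candidates %||% unique(markers$cell_type)
  genes <- rownames(e)
  sets <- lapply(candidates, function(ct) {
    intersect(unique(markers$gene[markers$cell_type == ct]), genes)
  })
  names(sets) <- candidates
  present <- vapply(sets, length, 1L) > 0
  if (!all(present)) {
    warning("candidates without matrix-present markers skipped: ",
            paste(candidates[!present], collapse = ", "))
    sets <- sets[present]
    candidates <- candidates[present]
  }
  if (!length(candidates)) stop("no candidate has markers in the matrix")
  ids <- sort(unique(cl))
  scores <- matrix(NA_real_, length(ids), length(candidates),
                   dimnames = list(ids, candidates))
  for (i in seq_along(ids)) {
    ranking <- cluster_logfc(e, cl, ids[i])
    for (ct in candidates) {
      scores[i, ct] <- tryCatch(
        gsea_es(ranking, sets[[ct]], weight_exponent),
        error = function(err) -Inf)
    }
  }
  best <- apply(scores, 1, which.max) # first max = marker-table order
  best_es <- scores[cbind(seq_along(ids), best)]
  label <- ifelse(best_es > 0, candidates[best], "Unknown")
  ann <- data.frame(cluster = ids, label = label, best_es = best_es,
                    provenance = "auto", stringsAsFactors = FALSE)
  if (!is.null(prior) && !force) {
    manual <- prior$provenance == "manual"
    idx <- match(prior$cluster[manual], ann$cluster)
    ok <- !is.na(idx)
    ann$label[idx[ok]] <- prior$label[manual][ok]
    ann$provenance[idx[ok]] <- "manual"
  }
  attr(ann, "scores") <- scores
  class(ann) <- c("cluster_annotation", class(ann))
  ann
}

#' Manually correct cluster labels
#'
#' @param a `cluster_annotation` from [annotate_clusters()].
#' @param overrides named vector/list, names = cluster ids, values =
#'   labels.
#' @return corrected annotation; overridden rows carry
#'   `provenance = "manual"`.
#' @export
correct_annotation <- function(a, overrides) {
  if (!length(overrides)) return(a)
  ids <- as.integer(names(overrides))
  missing <- setdiff(ids, a$cluster)
  if (length(missing))
    stop("unknown cluster id(s): ", paste(missing, collapse = ", "))
  idx <- match(ids, a$cluster)
  a$label[idx] <- unlist(overrides, use.names = FALSE)
  a$provenance[idx] <- "manual"
  a
}

#' Cell-type distribution per sample group
#'
#' Percentage of each annotated cell type within each design group; with
#' no design table, a single `"all"` group covers the dataset. Per-group
#' percentages sum to 100.
#'
#' @param a `cluster_annotation`.
#' @param cl named integer cluster assignment.
#' @param design optional data.frame (cell, sample, group).
#' @return data.frame (group, cell_type, percentage).
#' @export
cell_distribution <- function(a, cl, design = NULL) {
  label <- a$label[match(cl, a$cluster)]
  group <- if (is.null(design)) rep("all", length(cl)) else {
    g <- design$group[match(names(cl), design$cell)]
    if (anyNA(g)) stop("design table is missing ",
                       sum(is.na(g)), " barcodes")
    g
  }
  tab <- table(group, label)
  pct <- 100 * prop.table(tab, margin = 1)
  out <- as.data.frame(pct, stringsAsFactors = FALSE)
  names(out) <- c("group", "cell_type", "percentage")
  out[order(out$group, out$cell_type), , drop = FALSE]
}

#' EMT and proliferation scores
#'
#' Min-max normalizes every gene of the two sets across the whole dataset
#' to `[0, 1]` (constant genes map to 0) and averages over each set's
#' genes per selected cell, yielding scores bounded in `[0, 1]`.
#'
#' @param e genes x cells expression matrix.
#' @param cells barcodes to score (default: all).
#' @param emt_set,pro_set gene symbol vectors (e.g. hallmark
#'   epithelial-mesenchymal-transition and E2F-target sets read from GMT).
#' @return data.frame (cell, emt, pro).
#' @export
emt_pro_score <- function(e, cells = colnames(e), emt_set, pro_set) {
  x <- as_dense(e)
  score_one <- function(set, nm) {
    g <- intersect(set, rownames(x))
    if (!length(g)) stop("gene set '", nm, "' does not intersect the matrix")
    sub <- x[g, , drop = FALSE]
    rng <- apply(sub, 1, range)
    span <- rng[2, ] - rng[1, ]
    norm <- (sub - rng[1, ]) / ifelse(span > 0, span, 1)
    norm[span == 0, ] <- 0
    colMeans(norm[, cells, drop = FALSE])
  }
  data.frame(cell = cells,
             emt = unname(score_one(emt_set, "EMT")),
             pro = unname(score_one(pro_set, "PRO")),
             stringsAsFactors = FALSE)
}
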