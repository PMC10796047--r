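# Quality control, normalization, imputation, variable-gene selection,
# embedding and clustering. Everything downstream consumes the normalized
# matrix plus the cluster assignment produced here.

#' Quality-control filter on cells
#'
#' Keeps cells whose detected gene count (counts > 0) lies in
#' `[min_genes, max_genes]` and whose mitochondrial count fraction is at
#' most `max_mito_frac`. The gene axis is untouched.
#'
#' @param m genes x cells count matrix.
#' @param min_genes,max_genes detected-gene bounds (defaults 200 / 7500).
#' @param max_mito_frac maximum mitochondrial fraction of total counts
#'   (default 0.10).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return the filtered count matrix (same class as input).
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 7500,
                      max_mito_frac = 0.10, mito_prefix = "MT-") {
  stopifnot(min_genes > 0, max_genes > min_genes, max_mito_frac > 0)
  assert_counts(m)
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito_genes <- startsWith(rownames(m), mito_prefix)
  mito <- if (any(mito_genes))
    Matrix::colSums(m[mito_genes, , drop = FALSE]) else numeric(ncol(m))
  frac <- ifelse(total > 0, mito / total, 0)
  pass_lo <- detected >= min_genes
  pass_hi <- detected <= max_genes
  pass_mt <- frac <= max_mito_frac
  keep <- pass_lo & pass_hi & pass_mt
  if (!any(keep))
    stop("all cells removed by QC (", sum(!pass_lo), " below min_genes, ",
         sum(!pass_hi), " above max_genes, ", sum(!pass_mt),
         " above max_mito_frac)")
  m[, keep, drop = FALSE]
}

#' Variance-stabilizing normalization (Pearson residuals)
#'
#' Computes analytic Pearson residuals under a negative-binomial count
#' model with a sequencing-depth offset: the expected count of gene g in
#' cell j is `mu_gj = p_g * depth_j` with `p_g` the gene's share of total
#' counts, and the residual is `(x - mu) / sqrt(mu + mu^2/theta)`.
#' Residuals are clipped to `±sqrt(n_cells)`; all-zero genes map to
#' all-zero rows. Per-gene residual variance is approximately 1 for genes
#' that only track sequencing depth, so biological signal stands out as
#' excess variance.
#'
#' @param m QC-filtered genes x cells count matrix (>= 2 cells).
#' @param theta negative-binomial inverse-dispersion (default 100; large
#'   values approach Poisson residuals).
#' @return dense numeric matrix with attribute `provenance = "normalized"`.
#' @export
normalize_expr <- function(m, theta = 100) {
  assert_counts(m)
  if (ncol(m) < 2) stop("normalization needs at least 2 cells")
  x <- as_dense(m)
  depth <- colSums(x)
  total <- sum(depth)
  if (total == 0) {
    res <- x * 0
  } else {
    p <- rowSums(x) / total
    mu <- outer(p, depth)
    denom <- sqrt(mu + mu^2 / theta)
    res <- (x - mu) / denom
    res[denom == 0] <- 0
    clip <- sqrt(ncol(x))
    res[res > clip] <- clip
    res[res < -clip] <- -clip
  }
  dimnames(res) <- dimnames(x)
  attr(res, "provenance") <- "normalized"
  res
}

#' Low-rank imputation with error-quantile thresholding
#'
#' Reconstructs the expression matrix from its top `rank` singular
#' components, then uses the distribution of negative reconstructed values
#' in each gene (which can only arise from reconstruction error, the input
#' being nonnegative) to learn a per-gene magnitude threshold: entries
#' smaller in magnitude than the `error_quantile` of the gene's negative
#' magnitudes are reset to 0, and remaining negatives are clamped to 0.
#'
#' @param e nonnegative genes x cells expression matrix.
#' @param rank number of singular components, or `"auto"` to place the cut
#'   at the largest gap in the top-100 singular values.
#' @param error_quantile quantile of per-gene negative reconstruction
#'   magnitudes used as the zeroing threshold (default 1 = the largest).
#' @return imputed matrix with attribute `provenance = "imputed"`.
#' @export
impute_lowrank <- function(e, rank = "auto", error_quantile = 1) {
  x <- as_dense(e)
  kmax <- min(dim(x)) - 1L
  if (kmax < 1) stop("matrix too small for low-rank imputation")
  if (all(x == 0)) {
    out <- x
    attr(out, "provenance") <- "imputed"
    return(out)
  }
  sv <- svd(x)
  if (identical(rank, "auto")) {
    d <- sv$d[seq_len(min(100, length(sv$d)))]
    gaps <- -diff(d)
    rank <- if (length(gaps)) which.max(gaps) else 1L
  }
  rank <- as.integer(rank)
  if (rank >= min(dim(x))) stop("rank must be < min(genes, cells)")
  k <- seq_len(rank)
  recon <- sv$u[, k, drop = FALSE] %*%
    (sv$d[k] * t(sv$v[, k, drop = FALSE]))
  for (g in seq_len(nrow(recon))) {
    neg <- recon[g, recon[g, ] < 0]
    if (length(neg)) {
      thr <- stats::quantile(abs(neg), error_quantile, names = FALSE)
      recon[g, abs(recon[g, ]) < thr] <- 0
    }
  }
  recon[recon < 0] <- 0
  dimnames(recon) <- dimnames(x)
  attr(recon, "provenance") <- "imputed"
  recon
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their (already variance-stabilized,
#' clipped) expression values and returns the top `n`. Ties are broken by
#' gene symbol so the output is deterministic.
#'
#' @param e normalized genes x cells matrix.
#' @param n number of genes to keep (default 3000, capped at the gene
#'   count).
#' @return character vector of gene symbols, by decreasing variance.
#' @export
select_hvg <- function(e, n = 3000) {
  x <- as_dense(e)
  if (n > nrow(x)) stop("n exceeds the gene count")
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Principal-component embedding
#'
#' PCA on the selected genes (cells as observations, centered). Component
#' signs are fixed by making each component's largest-magnitude gene
#' loading positive, so the embedding is deterministic.
#'
#' @param e normalized genes x cells matrix.
#' @param genes genes to use (e.g. from [select_hvg()]).
#' @param n_pcs number of components (default 50, capped by the data).
#' @return cells x d matrix of class `embedding` with attribute
#'   `kind = "pca"`.
#' @export
embed_pca <- function(e, genes = rownames(e), n_pcs = 50) {
  x <- t(as_dense(e)[genes, , drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  if (n_pcs < 2) stop("need at least 2 principal components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, TRUE)
  scores <- pc$x
  scores[, flip] <- -scores[, flip]
  attr(scores, "kind") <- "pca"
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  class(scores) <- c("embedding", class(scores))
  scores
}

#' UMAP embedding of a PCA representation
#'
#' @param p cells x d PCA embedding.
#' @param n_use number of leading components to use; values outside
#'   `[10, 50]` are clamped with a warning (mirroring the interactive
#'   range), then capped at `ncol(p)`.
#' @param seed RNG seed; identical seeds give identical coordinates.
#' @param n_neighbors UMAP neighborhood size.
#' @return cells x 2 matrix with attribute `kind = "umap"`.
#' @export
embed_umap <- function(p, n_use = 30, seed = 0, n_neighbors = 15) {
  if (n_use < 10 || n_use > 50) {
    warning("n_use clamped into [10, 50]")
    n_use <- min(max(n_use, 10), 50)
  }
  n_use <- min(n_use, ncol(p))
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("embed_umap requires the 'uwot' package")
  coords <- with_seed(seed, uwot::umap(
    unclass(p)[, seq_len(n_use), drop = FALSE],
    n_neighbors = min(n_neighbors, nrow(p) - 1),
    n_threads = 1, n_sgd_threads = 1))
  rownames(coords) <- rownames(p)
  attr(coords, "kind") <- "umap"
  coords
}

# k nearest neighbors (euclidean, brute force), self excluded.
knn_indices <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Graph-based cell clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding, weights edges by
#' the Jaccard overlap of neighborhoods (shared nearest neighbors), and
#' runs Louvain community detection at the given resolution. Cluster ids
#' are relabeled 0..K-1 by decreasing size (ties by smallest member
#' barcode) so labels are deterministic.
#'
#' @param p cells x d embedding (rows named by barcode).
#' @param k_neighbors neighborhood size (default 20; must be < n_cells).
#' @param resolution Louvain resolution in `[0.1, 2]`; more clusters at
#'   higher values.
#' @param seed RNG seed for Louvain.
#' @param prune drop shared-neighbor edges with Jaccard below this value.
#' @return named integer vector (barcode -> cluster id) with attribute
#'   `resolution`.
#' @export
cluster_cells <- function(p, k_neighbors = 20, resolution = 0.5, seed = 0,
                          prune = 1 / 15) {
  x <- unclass(p)
  n <- nrow(x)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the cell count")
  nn <- knn_indices(x, k_neighbors)
  # SNN: Jaccard overlap of the two neighborhoods for each kNN edge
  pairs <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  pairs <- t(apply(pairs, 1, sort))
  pairs <- unique(pairs)
  w <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- nn[pairs[i, 1], ]
    b <- nn[pairs[i, 2], ]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  keep <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed, igraph::cluster_louvain(
    g, weights = w[keep], resolution = resolution))
  memb <- igraph::membership(comm)
  cl <- integer(n)
  cl[as.integer(names(memb))] <- as.integer(memb)
  barcodes <- rownames(x) %||% as.character(seq_len(n))
  # relabel by decreasing size, ties by smallest member barcode
  sizes <- table(cl)
  firsts <- vapply(names(sizes), function(k) min(barcodes[cl == as.integer(k)]),
                   "")
  ord <- names(sizes)[order(-as.vector(sizes), firsts)]
  out <- match(as.character(cl), ord) - 1L
  names(out) <- barcodes
  attr(out, "resolution") <- resolution
  out
}

#' Per-cluster summary for one gene
#'
#' Tabular replacement for violin/feature plots: mean expression and the
#' fraction of expressing cells (value > 0) per cluster.
#'
#' @param e genes x cells expression matrix.
#' @param cl named integer cluster assignment (barcode -> cluster).
#' @param gene gene symbol.
#' @return data.frame (cluster, mean_expr, frac_expressing).
#' @export
gene_feature_summary <- function(e, cl, gene) {
  x <- as_dense(e)
  if (!gene %in% rownames(x)) {
    near <- utils::head(agrep(gene, rownames(x), max.distance = 0.2,
                              value = TRUE), 5)
    stop("gene '", gene, "' not in matrix",
         if (length(near)) paste0("; close matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  v <- x[gene, names(cl)]
  ids <- sort(unique(cl))
  data.frame(
    cluster = ids,
    mean_expr = vapply(ids, function(k) mean(v[cl == k]), 0),
    frac_expressing = vapply(ids, function(k) mean(v[cl == k] > 0), 0))
}
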