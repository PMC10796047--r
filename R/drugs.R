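# Signature-reversal drug ranking against a connectivity-map style drug
# rank matrix, target-overlap lookup, cross-GSEA similarity, affinity
# propagation, and Tanimoto fingerprint clustering.

#' Build a drug rank matrix from perturbation signatures
#'
#' Per drug, genes are ranked decreasing by the differential-expression
#' statistic (rank 1 = most up-regulated); replicate columns sharing a
#' drug name are averaged before ranking. Ties break by gene symbol.
#'
#' @param signatures numeric genes x columns matrix; column names are drug
#'   ids (repeats = replicates).
#' @return integer matrix genes x drugs; every column is a permutation of
#'   `1..n_genes`.
#' @export
build_drug_rank_matrix <- function(signatures) {
  if (anyNA(signatures)) stop("signature matrix contains missing entries")
  drugs <- unique(colnames(signatures))
  if (is.null(drugs)) stop("signature matrix needs drug column names")
  out <- matrix(0L, nrow(signatures), length(drugs),
                dimnames = list(rownames(signatures), drugs))
  for (d in drugs) {
    v <- rowMeans(signatures[, colnames(signatures) == d, drop = FALSE])
    out[order(-v, rownames(signatures)), d] <- seq_len(nrow(signatures))
  }
  validate_rank_matrix(out)
  out
}

# Ranked gene list (names ordered by rank, descending pseudo-statistic)
# for one drug column of a rank matrix.
rank_column_list <- function(m, drug) {
  ord <- order(m[, drug])
  stats::setNames(as.numeric(rev(seq_len(nrow(m)))), rownames(m)[ord])
}

#' Rank drugs by signature reversal
#'
#' Scores the up-regulated gene set of a communication network against
#' every drug's ranked perturbation list with the unweighted (p = 0)
#' running-sum enrichment score. Drugs whose signatures push those genes
#' to the bottom of their ranking get strongly negative scores and are
#' candidate inhibitors; the `K` lowest-scoring drugs are returned,
#' ascending.
#'
#' @param up_genes up-regulated gene set (must intersect the matrix
#'   genes).
#' @param m drug rank matrix (genes x drugs).
#' @param K number of top drugs to return (default 30, capped).
#' @return data.frame of class `drug_scores` (drug, es, rank), sorted by
#'   es ascending (ties by drug id).
#' @export
signature_drug_discovery <- function(up_genes, m, K = 30) {
  up <- intersect(unique(up_genes), rownames(m))
  if (!length(up)) stop("up-regulated gene set does not intersect the ",
                        "rank matrix genes")
  if (length(up) >= nrow(m)) stop("gene set covers all matrix genes")
  es <- vapply(colnames(m), function(d) {
    gsea_es(rank_column_list(m, d), up, weight_exponent = 0)
  }, 0)
  ord <- order(es, names(es))
  out <- data.frame(drug = names(es)[ord], es = unname(es[ord]),
                    rank = seq_along(es), stringsAsFactors = FALSE)
  out <- out[seq_len(min(K, nrow(out))), , drop = FALSE]
  class(out) <- c("drug_scores", class(out))
  out
}

#' Drugs targeting network genes
#'
#' @param network_genes gene symbols of a communication network.
#' @param targets named list drug -> target gene set (e.g.
#'   `read_drug_targets()$targets`).
#' @return named list drug -> matched targets (drugs with none omitted).
#' @export
drugs_by_target <- function(network_genes, targets) {
  hits <- lapply(targets, intersect, x = network_genes)
  Filter(length, hits)
}

#' Cross-GSEA drug similarity matrix
#'
#' The similarity of drug i to drug j scores drug i's signature genes
#' against drug j's ranking: the top `n_sig` up-ranked and top `n_sig`
#' down-ranked genes of drug i form two sets, and
#' `S[i,j] = ES(up_i | j) - ES(down_i | j)` (the connectivity-map
#' reversal convention; `strategy = "up-only"` uses the up set alone).
#' The matrix is generally not symmetric.
#'
#' @param m drug rank matrix.
#' @param top_drugs drug ids to compare (default: all columns).
#' @param n_sig signature width per direction (default 150; requires
#'   `n_genes >= 2 * n_sig`).
#' @param strategy `"difference"` or `"up-only"`.
#' @return K x K numeric matrix with attribute `kind = "cross-gsea"`.
#' @export
cross_gsea_similarity <- function(m, top_drugs = colnames(m), n_sig = 150,
                                  strategy = c("difference", "up-only")) {
  strategy <- match.arg(strategy)
  if (nrow(m) < 2 * n_sig)
    stop("need at least 2 * n_sig genes in the rank matrix")
  k <- length(top_drugs)
  up_sets <- lapply(top_drugs, function(d) rownames(m)[m[, d] <= n_sig])
  dn_sets <- lapply(top_drugs, function(d)
    rownames(m)[m[, d] > nrow(m) - n_sig])
  rankings <- lapply(top_drugs, function(d) rank_column_list(m, d))
  S <- matrix(0, k, k, dimnames = list(top_drugs, top_drugs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      s <- gsea_es(rankings[[j]], up_sets[[i]], weight_exponent = 0)
      if (strategy == "difference")
        s <- s - gsea_es(rankings[[j]], dn_sets[[i]], weight_exponent = 0)
      S[i, j] <- s
    }
  }
  attr(S, "kind") <- "cross-gsea"
  S
}

#' Affinity-propagation clustering of a similarity matrix
#'
#' Frey-Dueck message passing. Asymmetric input is symmetrized as
#' `(S + t(S)) / 2`; the shared preference (self-similarity) is the
#' median of the off-diagonal similarities. Deterministic: no noise is
#' injected, and convergence means the exemplar set is stable for
#' `conv_iter` sweeps. On non-convergence the run is retried once with
#' damping 0.9 (with a warning). If message passing identifies no
#' exemplar (e.g. an all-equal similarity matrix has no structure), all
#' points form one cluster around the most central point.
#'
#' @param s K x K similarity matrix (K >= 2), row/col names = item ids.
#' @param damping message damping in `[0.5, 1)` (default 0.5).
#' @param max_iter maximum sweeps (default 1000).
#' @param conv_iter sweeps of unchanged exemplars declaring convergence.
#' @param preference scalar self-similarity; default median off-diagonal.
#' @return list with `labels` (named integer, 1..n_clusters), `exemplars`
#'   (item ids), `converged`.
#' @export
ap_cluster <- function(s, damping = 0.5, max_iter = 1000, conv_iter = 50,
                       preference = NULL) {
  n <- nrow(s)
  stopifnot(n >= 2, ncol(s) == n)
  ids <- rownames(s) %||% as.character(seq_len(n))
  S <- (unclass(s) + t(unclass(s))) / 2
  off <- S[row(S) != col(S)]
  if (max(off) - min(off) == 0) { # structureless: every grouping is equal
    return(list(labels = stats::setNames(rep(1L, n), ids),
                exemplars = ids[1], converged = TRUE))
  }
  diag(S) <- preference %||% stats::median(off)
  # break exact message-passing ties (symmetric inputs oscillate
  # otherwise); the jitter is deterministic in the input, orders of
  # magnitude below any real similarity difference
  span <- max(S) - min(S)
  if (span == 0) span <- 1
  S <- S + span * 1e-9 * with_seed(0, matrix(stats::rnorm(n * n), n, n))
  run <- function(lam) {
    R <- A <- matrix(0, n, n)
    stable <- 0
    last <- integer(0)
    for (it in seq_len(max_iter)) {
      # responsibilities
      AS <- A + S
      m1 <- apply(AS, 1, max)
      which1 <- max.col(AS, ties.method = "first")
      AS2 <- AS
      AS2[cbind(seq_len(n), which1)] <- -Inf
      m2 <- apply(AS2, 1, max)
      Rnew <- S - m1
      Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - m2
      R <- lam * R + (1 - lam) * Rnew
      # availabilities
      Rp <- pmax(R, 0)
      diag(Rp) <- diag(R)
      cs <- colSums(Rp)
      Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
      dA <- diag(Anew)
      Anew <- pmin(Anew, 0)
      diag(Anew) <- dA
      A <- lam * A + (1 - lam) * Anew
      ex <- which(diag(R) + diag(A) > 0)
      if (identical(ex, last)) stable <- stable + 1 else stable <- 0
      last <- ex
      if (stable >= conv_iter && length(ex)) break
    }
    list(ex = last, converged = stable >= conv_iter)
  }
  res <- run(damping)
  if (!res$converged || !length(res$ex)) {
    warning("affinity propagation did not converge; retrying with ",
            "damping 0.9")
    res <- run(0.9)
  }
  if (!length(res$ex)) { # structureless input: one cluster
    center <- which.max(colSums(S))
    labels <- stats::setNames(rep(1L, n), ids)
    return(list(labels = labels, exemplars = ids[center],
                converged = res$converged))
  }
  ex <- res$ex
  assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign[ex] <- ex
  labels <- stats::setNames(match(assign, sort(unique(assign))), ids)
  list(labels = labels, exemplars = ids[sort(unique(assign))],
       converged = res$converged)
}

#' Hashed-path chemical fingerprint from SMILES
#'
#' Fixed-length bit set over hashed linear substructure paths (OpenBabel
#' FP2 via ChemmineOB; 1024 bits). Only bit-set semantics are relied on,
#' so any fingerprinter of the same shape can substitute.
#'
#' @param smiles a SMILES string.
#' @param drug drug id used in error messages.
#' @return logical vector of length 1024.
#' @export
smiles_fingerprint <- function(smiles, drug = smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("smiles_fingerprint requires the 'ChemmineOB' package")
  fp <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\t", drug),
                                  identity)
    ChemmineOB::fingerprint_OB(mol, "FP2")
  }, error = function(e) NULL)
  if (is.null(fp) || length(fp) == 0)
    stop("unparseable SMILES for drug '", drug, "': ", smiles)
  as.logical(fp != 0)
}

#' Tanimoto similarity of two fingerprints
#'
#' `c / (a + b - c)` with a, b the set bit counts and c the shared bits;
#' two empty fingerprints are identical by convention (similarity 1).
#'
#' @param a,b logical bit vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  ca <- sum(a); cb <- sum(b); cc <- sum(a & b)
  if (ca + cb == 0) return(1)
  cc / (ca + cb - cc)
}

#' Cluster drugs by chemical structure
#'
#' Computes pairwise Tanimoto similarities over fingerprints and runs the
#' same affinity-propagation engine as [ap_cluster()].
#'
#' @param smiles named character vector (drug id -> SMILES), length >= 2.
#' @param ... passed to [ap_cluster()].
#' @return list with `similarity` (symmetric, unit diagonal, attribute
#'   `kind = "tanimoto"`), `labels`, `exemplars`.
#' @export
fingerprint_cluster <- function(smiles, ...) {
  if (length(smiles) < 2) stop("need at least 2 drugs with SMILES")
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  fps <- mapply(smiles_fingerprint, smiles, ids, SIMPLIFY = FALSE)
  n <- length(fps)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  attr(S, "kind") <- "tanimoto"
  cl <- ap_cluster(S, ...)
  list(similarity = S, labels = cl$labels, exemplars = cl$exemplars)
}
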