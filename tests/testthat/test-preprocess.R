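# Build a QC toy with prescribed detected-gene counts and mitochondrial
# fractions; genes beyond the detected count stay zero.
qc_toy <- function() {
  n_genes <- 8000
  genes <- c(paste0("MT-", 1:10), sprintf("G%04d", seq_len(n_genes - 10)))
  m <- matrix(0L, n_genes, 5,
              dimnames = list(genes, paste0("cell", 1:5)))
  fill <- function(j, detected, mito_counts = 0) {
    # mito genes first when a mito fraction is requested
    n_mito <- if (mito_counts > 0) 1 else 0
    if (n_mito) m[1, j] <<- as.integer(mito_counts)
    idx <- 10 + seq_len(detected - n_mito)
    m[idx, j] <<- 1L
  }
  fill(1, 150)
  fill(2, 300)
  fill(3, 7600)
  # 500 detected; mito counts = 12% of total: total t, mito = 0.12 t
  # choose 499 ones + mito 68 -> total 567, 68/567 = 0.1199...
  m[1, 4] <- 69L; m[10 + seq_len(499), 4] <- 1L # 69/568 = 12.1%
  m[1, 5] <- 26L; m[10 + seq_len(499), 5] <- 1L # 26/525 = 4.95%
  m
}

test_that("QC keeps exactly the cells inside all three rules", {
  m <- qc_toy()
  kept <- qc_filter(m)
  expect_equal(colnames(kept), c("cell2", "cell5"))
  expect_equal(nrow(kept), nrow(m)) # gene axis untouched
  # idempotent
  expect_equal(colnames(qc_filter(kept)), colnames(kept))
  # boundary cases from the rules themselves
  expect_false("cell1" %in% colnames(kept)) # 150 detected < 200
  expect_error(qc_filter(m[, 1, drop = FALSE]), "all cells removed")
})

test_that("normalization yields unit-scale residuals under a depth model", {
  set.seed(7)
  n_genes <- 300; n_cells <- 200
  depth <- exp(rnorm(n_cells, log(2000), 0.3))
  p <- rgamma(n_genes, 2, 2); p <- p / sum(p)
  mu <- outer(p, depth)
  m <- matrix(rpois(length(mu), mu), n_genes, n_cells,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("C%03d", 1:n_cells)))
  e <- normalize_expr(m)
  v <- apply(e, 1, var)
  expect_gte(mean(v >= 0.5 & v <= 2.0), 0.9)
  expect_true(all(abs(e) <= sqrt(n_cells) + 1e-12))
  expect_identical(attr(e, "provenance"), "normalized")
})

test_that("all-zero genes map to all-zero residuals", {
  m <- rbind(GA = c(0L, 0L), GB = c(5L, 3L), GC = c(0L, 1L))
  colnames(m) <- c("c1", "c2")
  e <- normalize_expr(m)
  expect_true(all(e["GA", ] == 0))
  expect_false(all(e["GC", ] == 0)) # expressed gene has signal
  z <- matrix(0L, 2, 3, dimnames = list(c("G1", "G2"), c("a", "b", "c")))
  expect_true(all(normalize_expr(z) == 0))
  expect_error(normalize_expr(m[, 1, drop = FALSE]), "2 cells")
})

test_that("a planted subpopulation gene has the top residual variance", {
  set.seed(11)
  n_genes <- 100; n_cells <- 150
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("C%03d", 1:n_cells)))
  m["G050", 1:50] <- rpois(50, 50) # 10x subpopulation, constant depth model
  e <- normalize_expr(m)
  v <- apply(e, 1, var)
  expect_equal(names(which.max(v)), "G050")
})

test_that("low-rank imputation reconstructs exact low-rank input", {
  u <- c(1, 2, 3, 4); v <- c(2, 1, 3)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("G", 1:4), paste0("C", 1:3))
  out <- impute_lowrank(m, rank = 1)
  expect_equal(out, m, ignore_attr = TRUE, tolerance = 1e-8)
  expect_identical(attr(out, "provenance"), "imputed")

  z <- matrix(0, 3, 3, dimnames = list(paste0("G", 1:3), paste0("C", 1:3)))
  expect_true(all(impute_lowrank(z, rank = 1) == 0))
  expect_error(impute_lowrank(m, rank = 3), "rank")
})

test_that("imputation restores planted dropout in rank-2 structure", {
  set.seed(3)
  u1 <- runif(60, 1, 2); v1 <- runif(50, 1, 2)
  u2 <- runif(60, 1, 2); v2 <- runif(50, 1, 2)
  truth <- outer(u1, v1) + outer(u2, v2)
  dimnames(truth) <- list(sprintf("G%02d", 1:60), sprintf("C%02d", 1:50))
  drop_idx <- sample(length(truth), 90)
  corrupted <- truth
  corrupted[drop_idx] <- 0
  out <- impute_lowrank(corrupted, rank = 2)
  rel_err <- abs(out[drop_idx] - truth[drop_idx]) / truth[drop_idx]
  expect_gte(mean(rel_err <= 0.2), 0.8)
  expect_true(all(out >= 0))
})

test_that("variable-gene selection ranks by variance with stable ties", {
  set.seed(5)
  e <- matrix(rnorm(40 * 30, sd = 0.1), 40, 30,
              dimnames = list(sprintf("G%02d", 1:40),
                              sprintf("C%02d", 1:30)))
  e["G07", ] <- c(rep(-3, 15), rep(3, 15)) # planted bimodal gene
  expect_equal(select_hvg(e, 1), "G07")
  expect_equal(length(select_hvg(e, 40)), 40)
  # exact ties resolve lexicographically
  tied <- rbind(B = c(1, -1, 1, -1), A = c(-1, 1, -1, 1),
                C = c(0, 0, 0, 0))
  colnames(tied) <- paste0("c", 1:4)
  expect_equal(select_hvg(tied, 2), c("A", "B"))
})

test_that("PCA captures a line in one component with fixed signs", {
  t_par <- seq(-5, 5, length.out = 40)
  dirv <- c(1, 2, 3, 4, 5, 6)
  x <- outer(dirv, t_par) # genes x cells, rank 1
  dimnames(x) <- list(paste0("G", 1:6), sprintf("C%02d", 1:40))
  p <- embed_pca(x, n_pcs = 3)
  v <- attr(p, "sdev")^2
  expect_gte(v[1] / sum(v), 0.999)
  p2 <- embed_pca(x, n_pcs = 3)
  expect_identical(unclass(p), unclass(p2)) # deterministic incl. sign
})

test_that("umap is reproducible under a fixed seed", {
  skip_if_not_installed("uwot")
  x <- blob_matrix(n_per = 30, k = 2, n_genes = 40)
  p <- embed_pca(x, n_pcs = 10)
  u1 <- embed_umap(p, n_use = 10, seed = 4)
  u2 <- embed_umap(p, n_use = 10, seed = 4)
  expect_identical(u1, u2)
  expect_warning(embed_umap(p, n_use = 5, seed = 4), "clamped")
})

test_that("two separated blobs stay separated in the umap embedding", {
  skip_if_not_installed("uwot")
  x <- blob_matrix(n_per = 40, k = 2, n_genes = 40, sep = 8)
  truth <- attr(x, "truth")
  p <- embed_pca(x, n_pcs = 10)
  u <- embed_umap(p, n_use = 10, seed = 0)
  c1 <- colMeans(u[truth == 1, ]); c2 <- colMeans(u[truth == 2, ])
  r1 <- quantile(sqrt(rowSums((u[truth == 1, ] -
                                 rep(c1, each = sum(truth == 1)))^2)), 0.95)
  expect_gt(sqrt(sum((c1 - c2)^2)), r1)
})

test_that("clustering recovers planted populations and obeys resolution", {
  x <- blob_matrix(n_per = 40, k = 3, n_genes = 60, sep = 6)
  truth <- attr(x, "truth")
  p <- embed_pca(x, n_pcs = 10)
  cl <- cluster_cells(p, k_neighbors = 15, resolution = 0.5)
  expect_equal(length(unique(cl)), 3)
  expect_gte(ari(cl, truth), 0.95)
  expect_equal(sort(unique(cl)), 0:2) # contiguous ids from 0
  cl_lo <- cluster_cells(p, k_neighbors = 15, resolution = 0.1)
  cl_hi <- cluster_cells(p, k_neighbors = 15, resolution = 2.0)
  expect_lte(length(unique(cl_lo)), length(unique(cl_hi)))

  blob <- blob_matrix(n_per = 60, k = 1, n_genes = 40, sep = 0)
  pb <- embed_pca(blob, n_pcs = 10)
  expect_equal(length(unique(cluster_cells(pb, 15, resolution = 0.1))), 1)
  expect_error(cluster_cells(pb, k_neighbors = 100), "smaller")
})

test_that("gene feature summaries localize a planted marker", {
  x <- blob_matrix(n_per = 30, k = 3, n_genes = 60)
  truth <- attr(x, "truth")
  cl <- setNames(truth - 1L, colnames(x))
  x["G001", ] <- 0
  x["G001", cl == 2] <- 5
  s <- gene_feature_summary(x, cl, "G001")
  expect_equal(nrow(s), 3)
  expect_equal(s$frac_expressing[s$cluster != 2], c(0, 0))
  expect_equal(s$cluster[which.max(s$mean_expr)], 2)
  zero <- gene_feature_summary(x * 0, cl, "G001")
  expect_true(all(zero$mean_expr == 0))
  expect_error(gene_feature_summary(x, cl, "G0001"), "close matches")
})
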