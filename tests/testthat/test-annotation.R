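toy_expr <- function() {
  # 4 genes x 6 cells, two planted clusters
  e <- rbind(GA = c(2, 2, 2, 0.5, 0.5, 0.5),
             GB = c(0, 0, 0, 1, 1, 1),
             GC = c(1, 1, 1, 1, 1, 1),
             GD = c(0.2, 0.4, 0.6, 0.1, 0.2, 0.0))
  colnames(e) <- paste0("c", 1:6)
  e
}

test_that("cluster log fold change matches the mean-difference formula", {
  e <- toy_expr()
  cl <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), colnames(e))
  r <- cluster_logfc(e, cl, 0)
  expect_equal(r[["GA"]], 2.0 - 0.5)
  expect_equal(r[["GC"]], 0)
  # full ranking against hand-computed values, sorted decreasing
  expected <- c(GA = 1.5, GD = 0.4 - 0.1, GC = 0, GB = -1)
  expect_equal(r, expected[order(-expected, names(expected))])
  expect_error(cluster_logfc(e, setNames(rep(0L, 6), colnames(e)), 0),
               "every cell")
  expect_error(cluster_logfc(e, cl, 5), "empty")
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    r <- sort(rnorm(n), decreasing = TRUE)
    names(r) <- sprintf("G%02d", sample(n))
    set <- sample(names(r), sample(1:(n - 1), 1))
    for (p in c(0, 1)) {
      expect_equal(gsea_es(r, set, p), brute_es(r, set, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment score hits its extremes at the ranking ends", {
  r <- setNames(seq(5, 0.5, length.out = 10), paste0("G", 1:10))
  expect_equal(gsea_es(r, "G1"), 1) # single top gene peaks immediately
  es_last <- gsea_es(r, "G10")
  expect_lte(es_last, -(10 - 1) / 10) # deep negative excursion before hit
  expect_gte(es_last, -1)
  expect_error(gsea_es(r, "NOPE"), "intersect")
  # unweighted antisymmetry under ranking reversal
  set.seed(1)
  for (i in 1:20) {
    r2 <- setNames(sort(runif(20), decreasing = TRUE), sprintf("H%02d", 1:20))
    s <- sample(names(r2), 6)
    expect_equal(gsea_es(rev(r2), s, 0), -gsea_es(r2, s, 0),
                 tolerance = 1e-12)
  }
})

test_that("clusters are annotated by argmax marker enrichment", {
  set.seed(8)
  n_genes <- 60
  genes <- sprintf("G%02d", 1:n_genes)
  e <- matrix(rnorm(n_genes * 60, sd = 0.3), n_genes, 60,
              dimnames = list(genes, sprintf("c%02d", 1:60)))
  cl <- setNames(rep(0:2, each = 20), colnames(e))
  e[1:5, cl == 0] <- e[1:5, cl == 0] + 3   # TypeA markers G01..G05
  e[6:10, cl == 1] <- e[6:10, cl == 1] + 3 # TypeB markers G06..G10
  # cluster 2: no marker signal -> Unknown
  markers <- data.frame(
    cell_type = rep(c("TypeA", "TypeB"), each = 5),
    gene = genes[1:10], stringsAsFactors = FALSE)
  ann <- annotate_clusters(e, cl, markers)
  expect_equal(ann$label[ann$cluster == 0], "TypeA")
  expect_equal(ann$label[ann$cluster == 1], "TypeB")
  expect_equal(ann$label[ann$cluster == 2], "Unknown")
  expect_true(all(ann$provenance == "auto"))
  scores <- attr(ann, "scores")
  expect_true(all(scores >= -1 & scores <= 1))
})

test_that("a single candidate whose markers sink to the bottom is Unknown", {
  e <- toy_expr()
  cl <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), colnames(e))
  markers <- data.frame(cell_type = "TypeX", gene = "GB",
                        stringsAsFactors = FALSE)
  ann <- annotate_clusters(e, cl, markers) # GB is lowest-ranked in cluster 0
  expect_equal(ann$label[ann$cluster == 0], "Unknown")
  expect_warning(
    annotate_clusters(e, cl, data.frame(cell_type = c("TypeX", "Ghost"),
                                        gene = c("GA", "ZZZ"))),
    "skipped")
})

test_that("manual corrections persist through re-annotation", {
  e <- toy_expr()
  cl <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), colnames(e))
  markers <- data.frame(cell_type = "TypeA", gene = "GA",
                        stringsAsFactors = FALSE)
  ann <- annotate_clusters(e, cl, markers)
  fixed <- correct_annotation(ann, c("1" = "Ductal 2"))
  expect_equal(fixed$label[fixed$cluster == 1], "Ductal 2")
  expect_equal(fixed$provenance[fixed$cluster == 1], "manual")
  expect_equal(correct_annotation(ann, list()), ann)
  expect_error(correct_annotation(ann, c("9" = "X")), "unknown cluster")
  # re-run keeps the manual label unless forced
  again <- annotate_clusters(e, cl, markers, prior = fixed)
  expect_equal(again$label[again$cluster == 1], "Ductal 2")
  forced <- annotate_clusters(e, cl, markers, prior = fixed, force = TRUE)
  expect_equal(forced$provenance[forced$cluster == 1], "auto")
})

test_that("cell-type distributions are percentages that sum to 100", {
  cl <- setNames(c(rep(0L, 4), rep(1L, 6)), paste0("c", 1:10))
  ann <- data.frame(cluster = 0:1, label = c("TypeA", "TypeB"),
                    best_es = c(1, 1), provenance = "auto")
  d <- cell_distribution(ann, cl)
  expect_equal(unique(d$group), "all")
  expect_equal(d$percentage[d$cell_type == "TypeA"], 40)
  design <- data.frame(cell = names(cl),
                       sample = rep(c("s1", "s2"), 5),
                       group = rep(c("g1", "g2"), 5))
  d2 <- cell_distribution(ann, cl, design)
  sums <- tapply(d2$percentage, d2$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  set.seed(2)
  for (i in 1:5) { # conservation on random assignments
    cl_r <- setNames(sample(0:1, 10, TRUE), names(cl))
    dr <- cell_distribution(ann, cl_r, design)
    expect_true(all(abs(tapply(dr$percentage, dr$group, sum) - 100) < 1e-9))
  }
})

test_that("EMT/PRO scores are min-max bounded means", {
  e <- rbind(E1 = c(0, 5, 10), E2 = c(1, 3, 5), P1 = c(2, 2, 2),
             P2 = c(0, 1, 2))
  colnames(e) <- c("c1", "c2", "c3")
  s <- emt_pro_score(e, emt_set = c("E1", "E2"), pro_set = c("P1", "P2"))
  expect_equal(s$emt[s$cell == "c3"], 1) # at dataset max for every EMT gene
  expect_equal(s$emt[s$cell == "c1"], 0) # at dataset min
  # constant gene contributes 0: PRO of c3 = mean(0, 1)
  expect_equal(s$pro[s$cell == "c3"], 0.5)
  expect_true(all(s$emt >= 0 & s$emt <= 1 & s$pro >= 0 & s$pro <= 1))
  # three-gene set with normalized values {0, .5, 1} averages to 0.5
  e2 <- rbind(A = c(0, 10, 2), B = c(5, 0, 10), C = c(10, 0, 5),
              D = c(0, 1, 2))
  colnames(e2) <- c("x", "y", "z")
  s2 <- emt_pro_score(e2, cells = "x", emt_set = c("A", "B", "C"),
                      pro_set = "D")
  expect_equal(s2$emt, mean(c(0, 0.5, 1)))
  expect_error(emt_pro_score(e2, emt_set = "NOPE", pro_set = "D"), "EMT")
})
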