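toy_de <- function(genes, lfc, p = NULL) {
  if (is.null(p)) p <- rep(1e-6, length(genes))
  data.frame(gene = genes, logFC = lfc, p_wilcoxon = p, p_lrt = p,
             adj_p_wilcoxon = p, adj_p_lrt = p,
             is_up = lfc > 0.08 & p < 0.05, stringsAsFactors = FALSE)
}

test_that("ligand/receptor tiers follow the DE flags", {
  db <- lr_db(c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  de <- toy_de(c("L1", "L2", "R1", "ZZ"),
               c(0.2, 0.01, 0.5, 3),
               c(1e-6, 0.5, 1e-6, 1e-6))
  lr <- find_lr(de, db)
  expect_equal(lr$up_ligands, "L1") # significant and above threshold
  expect_equal(lr$expressed_ligands, c("L1", "L2")) # L2 only logFC > 0
  expect_equal(lr$up_receptors, "R1")
  expect_true(all(lr$up_ligands %in% lr$expressed_ligands))
  expect_false("ZZ" %in% unlist(lr)) # not in the database
})

test_that("the four upstream networks obey their set logic", {
  db <- lr_db(rep(c("L1", "L2", "L3"), each = 3),
              rep(c("R1", "R2", "R3"), times = 3))
  sender <- toy_de(c("L1", "L2"), c(0.5, 0.03)) # L1 up, L2 expressed-only
  receiver <- toy_de(c("R1", "R2"), c(0.4, 0.02)) # R1 up, R2 expressed-only
  up <- upstream_networks(sender, receiver, db)
  key <- function(e) paste(e$ligand, e$receptor)
  expect_equal(key(up$up_up), "L1 R1")
  expect_setequal(key(up$up_exp), c("L1 R1", "L1 R2"))
  expect_setequal(key(up$exp_up), c("L1 R1", "L2 R1"))
  expect_setequal(key(up$combined), c("L1 R1", "L1 R2", "L2 R1"))
  expect_true(all(key(up$up_up) %in% key(up$combined)))
  # absent from db -> nowhere
  sender2 <- toy_de("LX", 2)
  up2 <- upstream_networks(sender2, receiver, db)
  expect_equal(nrow(up2$combined), nrow(up2$exp_up))
})

test_that("edge weights reward strong fold changes", {
  expect_equal(edge_weight(0.5, 0.2), 2 + 5)
  expect_equal(edge_weight(1, -1), 2)
  expect_equal(edge_weight(0.5, 0), 2 + 1e6)
  expect_true(edge_weight(0.1, 0.1) > edge_weight(0.2, 0.1))
})

test_that("curated-graph downstream search keeps scoring shortest paths", {
  chain <- signaling_graph(data.frame(from = c("R", "A"), to = c("A", "B")))
  fc <- c(R = 0.3, A = 0.6, B = 0.9)
  d <- kegg_downstream("R", fc, chain, score_threshold = 0.5)
  expect_equal(length(d$paths), 1)
  expect_equal(d$paths[[1]]$nodes, c("R", "A", "B"))
  expect_equal(d$paths[[1]]$score, 0.6)
  expect_equal(length(kegg_downstream("R", fc, chain, 0.7)$paths), 0)
  expect_warning(kegg_downstream(c("R", "NOPE"), fc, chain, 0.5),
                 "skipped")
})

test_that("curated-graph search equals the exhaustive path oracle", {
  for (s in 1:12) {
    g <- random_dag(sample(6:12, 1), seed = s)
    set.seed(s + 100)
    fc <- setNames(rnorm(length(g$nodes), 0.2, 0.4), g$nodes)
    receptors <- g$nodes[1:2]
    thr <- 0.1
    d <- kegg_downstream(receptors, fc, g, thr)
    got <- sort(vapply(d$paths, function(p) path_key(p$nodes), ""))
    expect_equal(got, oracle_kegg(receptors, fc, g, thr))
  }
})

test_that("greedy dense-graph search matches a step-by-step oracle", {
  edges <- data.frame(
    from = c("R", "R", "A", "A", "B", "C", "C", "D", "E", "F", "G", "H",
             "B", "K"),
    to = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
           "K", "L"))
  g <- signaling_graph(edges, "string-like")
  for (s in 1:20) {
    set.seed(s)
    fc <- setNames(rnorm(length(g$nodes), 0.3, 0.5), g$nodes)
    got <- string_downstream("R", fc, g, k1 = 3, k2 = 3, N = 6)
    want <- oracle_string_one("R", fc, g, k1 = 3, k2 = 3, N = 6)
    expect_setequal(got$nodes, want$nodes)
    expect_equal(lapply(got$paths, `[[`, "nodes"),
                 lapply(want$trace, `[[`, "nodes"))
  }
})

test_that("dense-graph growth respects the width, depth and size bounds", {
  edges <- data.frame(
    from = rep(c("R", "A", "B", "C", "D"), each = 3),
    to = c("A", "B", "C", "B", "C", "D", "C", "D", "E", "D", "E", "F",
           "E", "F", "G"))
  g <- signaling_graph(edges, "string-like")
  set.seed(5)
  for (i in 1:10) {
    fc <- setNames(runif(length(g$nodes), -1, 1), g$nodes)
    k2 <- sample(2:4, 1); N <- sample(3:6, 1)
    d <- string_downstream("R", fc, g, k1 = 3, k2 = k2, N = N)
    expect_lte(length(d$nodes), N + k2 - 1)
    for (p in d$paths) expect_lte(length(p$nodes), k2)
  }
  # unreachable candidates leave the receptor alone
  lone <- signaling_graph(data.frame(from = "X", to = "Y"))
  lone$nodes <- c(lone$nodes, "R")
  d <- string_downstream("R", c(Y = 1), lone, k1 = 2, k2 = 3, N = 5)
  expect_equal(d$nodes, "R")
  # a single high-fc neighbor is added first
  star <- signaling_graph(data.frame(from = rep("R", 3),
                                     to = c("A", "B", "C")))
  d2 <- string_downstream("R", c(A = 0.1, B = 2, C = 0.2), star,
                          k1 = 1, k2 = 2, N = 2)
  expect_setequal(d2$nodes, c("R", "B"))
})

test_that("communication networks merge parts and flag TFs", {
  db <- lr_db(c("L1", "L2"), c("R1", "R1"))
  up <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R1"),
                   stringsAsFactors = FALSE)
  g <- signaling_graph(data.frame(from = c("R1", "A", "A", "B"),
                                  to = c("A", "B", "C", "D")))
  fc <- c(L1 = 0.5, L2 = 0.3, R1 = 0.4, A = 0.6, B = 0.2, C = 0.7,
          D = 0.9)
  down <- kegg_downstream("R1", fc, g, score_threshold = 0)
  tf <- data.frame(tf = "B", target = "D", stringsAsFactors = FALSE)
  net <- build_comm_network("S", "T", up, down, tf, fc)
  expect_setequal(net$nodes$gene,
                  union(c("L1", "L2", "R1"), down$nodes))
  expect_true(net$nodes$is_tf[net$nodes$gene == "B"])
  expect_false(any(net$nodes$is_tf[net$nodes$gene %in% c("L1", "C")]))
  expect_equal(net$nodes$fc[net$nodes$gene == "A"], 0.6)
  expect_equal(sum(net$edges$type == "lr"), 2)
  # every downstream node reachable from a receptor
  ig <- igraph::graph_from_data_frame(net$edges)
  reach <- names(igraph::subcomponent(ig, "R1", mode = "out"))
  expect_true(all(down$nodes %in% reach))
  # empty downstream -> upstream only
  empty <- kegg_downstream("R1", fc, g, score_threshold = 10)
  net2 <- build_comm_network("S", "T", up, empty, tf, fc)
  expect_setequal(net2$nodes$gene, c("L1", "L2", "R1"))
  expect_true(all(net2$edges$type == "lr"))
})

test_that("comm networks export to tsv and graphml", {
  dir <- withr::local_tempdir()
  db <- data.frame(ligand = "L1", receptor = "R1")
  g <- signaling_graph(data.frame(from = "R1", to = "A"))
  fc <- c(L1 = 1, R1 = 1, A = 1)
  net <- build_comm_network("S", "T", db,
                            kegg_downstream("R1", fc, g, 0),
                            data.frame(tf = character(0),
                                       target = character(0)), fc)
  write_comm_network(net, file.path(dir, "net"))
  expect_true(file.exists(file.path(dir, "net_nodes.tsv")))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  nodes <- read.delim(file.path(dir, "net_nodes.tsv"))
  expect_setequal(nodes$gene, c("L1", "R1", "A"))
})
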