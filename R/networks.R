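# Upstream ligand-receptor network construction between a sender and a
# receiver cell type, and downstream signaling discovery over KEGG-like
# (sparse, curated) and STRING-like (dense) background graphs. All path
# scores use the receiver contrast's fold changes; genes missing from the
# DE table count as fold change 0.

as_igraph <- function(g, weights = NULL) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  if (!is.null(weights)) igraph::E(ig)$weight <- weights
  ig
}

#' Edge weight from endpoint fold changes
#'
#' `w = 1/max(|fc_i|, eps) + 1/max(|fc_j|, eps)`: edges between strongly
#' regulated genes are cheap, so weighted shortest paths prefer routes
#' through high-|fc| genes.
#'
#' @param fc_i,fc_j fold changes of the edge's endpoints (vectorized).
#' @param eps guard against zero fold change (default 1e-6).
#' @return strictly positive weight(s).
#' @export
edge_weight <- function(fc_i, fc_j, eps = 1e-6) {
  1 / pmax(abs(fc_i), eps) + 1 / pmax(abs(fc_j), eps)
}

#' Split DE genes into ligand/receptor tiers
#'
#' Up-regulated ligands/receptors satisfy the full `is_up` criterion of
#' the DE table; expressed ligands/receptors only need logFC > 0, so the
#' up-regulated sets are subsets of the expressed sets.
#'
#' @param de `de_result` data.frame.
#' @param db `lr_db` database.
#' @return list `up_ligands`, `up_receptors`, `expressed_ligands`,
#'   `expressed_receptors`.
#' @export
find_lr <- function(de, db) {
  up <- de$gene[de$is_up]
  expressed <- de$gene[de$logFC > 0]
  list(up_ligands = intersect(up, db$ligands),
       up_receptors = intersect(up, db$receptors),
       expressed_ligands = intersect(expressed, db$ligands),
       expressed_receptors = intersect(expressed, db$receptors))
}

#' Four upstream ligand-receptor networks
#'
#' Database interactions whose ligand comes from the sender contrast and
#' receptor from the receiver contrast, in the four tier combinations:
#' up-ligand to expressed-receptor, expressed-ligand to up-receptor,
#' up-ligand to up-receptor, and their combined union.
#'
#' @param sender_de,receiver_de `de_result` tables computed at the same
#'   thresholds.
#' @param db `lr_db` database.
#' @return list of class `upstream_networks` with edge data.frames
#'   `up_exp`, `exp_up`, `up_up`, `combined`, plus the tier gene sets.
#' @export
upstream_networks <- function(sender_de, receiver_de, db) {
  s <- find_lr(sender_de, db)
  r <- find_lr(receiver_de, db)
  pick <- function(lig, rec) {
    e <- db$pairs[db$pairs$ligand %in% lig & db$pairs$receptor %in% rec, ,
                  drop = FALSE]
    rownames(e) <- NULL
    e
  }
  up_exp <- pick(s$up_ligands, r$expressed_receptors)
  exp_up <- pick(s$expressed_ligands, r$up_receptors)
  up_up <- pick(s$up_ligands, r$up_receptors)
  combined <- unique(rbind(up_exp, exp_up, up_up))
  rownames(combined) <- NULL
  structure(list(up_exp = up_exp, exp_up = exp_up, up_up = up_up,
                 combined = combined, sender_lr = s, receiver_lr = r),
            class = "upstream_networks")
}

#' @export
print.upstream_networks <- function(x, ...) {
  cat("upstream ligand-receptor networks:\n")
  for (nm in c("up_exp", "exp_up", "up_up", "combined"))
    cat(sprintf("  %-8s %d edges\n", nm, nrow(x[[nm]])))
  invisible(x)
}

# Distance matrix (rows/cols = g$nodes). weights=NULL -> unweighted BFS.
graph_distances <- function(g, weights = NULL) {
  ig <- as_igraph(g, weights)
  igraph::distances(ig, mode = "out",
                    weights = if (is.null(weights)) NA else weights)
}

# Lexicographically smallest minimum-cost path from `from` to `to`.
# D = full distance matrix, adj = list of out-neighbors, W = lookup of
# edge weights (NULL for unit). Greedy: at each step take the smallest
# symbol among successors that still lie on a minimum-cost path.
lex_shortest_path <- function(from, to, D, adj, wfun = NULL, tol = 1e-9) {
  total <- D[from, to]
  if (!is.finite(total)) return(NULL)
  path <- from
  v <- from
  acc <- 0
  while (v != to) {
    nbrs <- sort(adj[[v]])
    ok <- vapply(nbrs, function(u) {
      w <- if (is.null(wfun)) 1 else wfun(v, u)
      isTRUE(abs(acc + w + D[u, to] - total) <= tol * max(1, total))
    }, TRUE)
    if (!any(ok)) return(NULL) # numerically unreachable; should not happen
    u <- nbrs[ok][1]
    acc <- acc + (if (is.null(wfun)) 1 else wfun(v, u))
    path <- c(path, u)
    v <- u
  }
  path
}

adjacency_list <- function(g) {
  adj <- split(g$edges$to, factor(g$edges$from, levels = g$nodes))
  lapply(adj, as.character)
}

#' Path activation score
#' @param path character vector of gene symbols.
#' @param fc named fold-change vector (missing genes count as 0).
#' @return mean fold change over the path's nodes.
#' @export
path_score <- function(path, fc) mean(fc_lookup(fc, path))

#' Downstream signaling over a curated (KEGG-like) graph
#'
#' For every receptor and every target gene (a node without outgoing
#' signaling, i.e. out-degree 0 in the merged graph), finds the unweighted
#' shortest path (breadth-first; ties broken by the lexicographically
#' smallest node sequence), scores it by the mean fold change of its
#' nodes, and keeps paths scoring strictly above the threshold.
#'
#' @param receptors receptor gene symbols (graph-absent ones are skipped
#'   with a warning).
#' @param fc named fold-change vector for the receiver contrast.
#' @param g `signaling_graph`, kegg-like.
#' @param score_threshold keep paths with score > this value (default
#'   0.1).
#' @return list of class `downstream_network`: `paths` (each with
#'   `nodes`, `score`, `receptor`, `target`), `nodes`, `edges`.
#' @export
kegg_downstream <- function(receptors, fc, g, score_threshold = 0.1) {
  missing <- setdiff(receptors, g$nodes)
  if (length(missing)) {
    warning("receptors absent from graph skipped: ",
            paste(missing, collapse = ", "))
    receptors <- intersect(receptors, g$nodes)
  }
  outdeg <- table(factor(g$edges$from, levels = g$nodes))
  targets <- g$nodes[outdeg == 0]
  D <- graph_distances(g)
  adj <- adjacency_list(g)
  paths <- list()
  for (r in receptors) {
    for (t in setdiff(targets, r)) {
      p <- lex_shortest_path(r, t, D, adj)
      if (is.null(p)) next
      s <- path_score(p, fc)
      if (s > score_threshold)
        paths[[length(paths) + 1]] <- list(nodes = p, score = s,
                                           receptor = r, target = t)
    }
  }
  downstream_network(paths)
}

downstream_network <- function(paths) {
  nodes <- unique(unlist(lapply(paths, `[[`, "nodes")))
  edges <- unique(do.call(rbind, lapply(paths, function(p) {
    if (length(p$nodes) < 2) return(NULL)
    data.frame(from = p$nodes[-length(p$nodes)], to = p$nodes[-1],
               stringsAsFactors = FALSE)
  })))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0))
  rownames(edges) <- NULL
  structure(list(paths = paths, nodes = nodes %||% character(0),
                 edges = edges),
            class = "downstream_network")
}

#' @export
print.downstream_network <- function(x, ...) {
  cat("downstream signaling network:", length(x$paths), "paths,",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Greedy downstream discovery over a dense (STRING-like) graph
#'
#' Starting from each receptor as a one-node network, repeatedly: take the
#' `k1` highest-|fc| graph genes not yet in the network as candidates;
#' from every current network node compute the minimum-weight path (edge
#' weights from [edge_weight()]) to each candidate; discard paths with
#' more than `k2` nodes; score survivors by mean fold change and add the
#' single best path (ties: fewer nodes, then lexicographic node sequence,
#' then candidate symbol). Stop when the network reaches `N` nodes or no
#' admissible path remains; the final network is the union over receptors.
#'
#' @param receptors receptor gene symbols.
#' @param fc named fold-change vector.
#' @param g `signaling_graph`, string-like.
#' @param k1 candidate-set width (default 10).
#' @param k2 maximum path length in nodes (default 5).
#' @param N network node limit per receptor (default 50).
#' @param eps zero-fold-change guard for edge weights.
#' @return `downstream_network`; each added path is recorded with its
#'   score.
#' @export
string_downstream <- function(receptors, fc, g, k1 = 10, k2 = 5, N = 50,
                              eps = 1e-6) {
  stopifnot(k1 >= 1, k2 >= 1, N > 1)
  missing <- setdiff(receptors, g$nodes)
  if (length(missing)) {
    warning("receptors absent from graph skipped: ",
            paste(missing, collapse = ", "))
    receptors <- intersect(receptors, g$nodes)
  }
  node_fc <- stats::setNames(fc_lookup(fc, g$nodes), g$nodes)
  w <- edge_weight(node_fc[g$edges$from], node_fc[g$edges$to], eps)
  D <- graph_distances(g, weights = unname(w))
  adj <- adjacency_list(g)
  wfun <- function(a, b) edge_weight(node_fc[[a]], node_fc[[b]], eps)
  all_paths <- list()
  for (r in receptors) {
    net <- r
    repeat {
      if (length(net) >= N) break
      pool <- setdiff(g$nodes, net)
      if (!length(pool)) break
      ord <- order(-abs(node_fc[pool]), pool)
      cand <- pool[ord][seq_len(min(k1, length(pool)))]
      best <- NULL
      for (gk in sort(net)) {
        for (cj in sort(cand)) {
          p <- lex_shortest_path(gk, cj, D, adj, wfun)
          if (is.null(p) || length(p) > k2) next
          s <- path_score(p, node_fc)
          if (is.null(best) || s > best$score + 1e-12 ||
              (abs(s - best$score) <= 1e-12 &&
               (length(p) < length(best$nodes) ||
                (length(p) == length(best$nodes) &&
                 paste(p, collapse = "\r") <
                 paste(best$nodes, collapse = "\r"))))) {
            best <- list(nodes = p, score = s, receptor = r, target = cj)
          }
        }
      }
      if (is.null(best)) break
      all_paths[[length(all_paths) + 1]] <- best
      net <- union(net, best$nodes)
    }
  }
  dn <- downstream_network(all_paths)
  dn$nodes <- union(dn$nodes, intersect(receptors, g$nodes))
  dn
}

#' Assemble a sender-to-receiver communication network
#'
#' Merges the upstream ligand-receptor edges with each receptor's
#' downstream signaling network, flags transcription factors, and
#' annotates every node with its fold change.
#'
#' @param sender,receiver cell-type labels (metadata only).
#' @param up either an `upstream_networks` object (its `combined` edges
#'   are used) or a data.frame with columns `ligand`, `receptor`.
#' @param downstream `downstream_network` (possibly empty).
#' @param tf data.frame (tf, target) naming transcription factors.
#' @param fc named fold-change vector for the receiver contrast.
#' @return list of class `comm_network`: `nodes` (gene, fc, role, is_tf)
#'   and `edges` (from, to, type in lr/signaling).
#' @export
build_comm_network <- function(sender, receiver, up, downstream, tf, fc) {
  lr_edges <- if (inherits(up, "upstream_networks")) up$combined else up
  ligands <- unique(lr_edges$ligand)
  receptors <- unique(lr_edges$receptor)
  down_nodes <- setdiff(downstream$nodes, c(ligands, receptors))
  genes <- c(ligands, receptors, down_nodes)
  role <- c(rep("ligand", length(ligands)),
            rep("receptor", length(receptors)),
            rep("intermediate", length(down_nodes)))
  nodes <- data.frame(gene = genes, fc = fc_lookup(fc, genes), role = role,
                      is_tf = genes %in% unique(tf$tf),
                      stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(lr_edges)) data.frame(from = lr_edges$ligand,
                                   to = lr_edges$receptor, type = "lr",
                                   stringsAsFactors = FALSE),
    if (nrow(downstream$edges)) data.frame(from = downstream$edges$from,
                                           to = downstream$edges$to,
                                           type = "signaling",
                                           stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0))
  rownames(edges) <- NULL
  structure(list(sender = sender, receiver = receiver, nodes = nodes,
                 edges = edges),
            class = "comm_network")
}

#' @export
print.comm_network <- function(x, ...) {
  cat("communication network ", x$sender, " -> ", x$receiver, ": ",
      nrow(x$nodes), " nodes (", sum(x$nodes$role == "ligand"), " ligands, ",
      sum(x$nodes$role == "receptor"), " receptors, ",
      sum(x$nodes$is_tf), " TFs), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Write a communication network as node/edge TSV and GraphML
#' @param net `comm_network`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @export
write_comm_network <- function(net, prefix) {
  utils::write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ig <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                      vertices = net$nodes)
  igraph::write_graph(ig, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
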