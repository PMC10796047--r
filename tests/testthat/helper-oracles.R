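# Independent oracles: deliberately plain re-derivations (loops,
# enumeration, exhaustive search) of quantities the package computes by
# other means.

# Running-sum enrichment score as an explicit walk down the ranking.
brute_es <- function(ranking, gene_set, p = 1) {
  hit <- names(ranking) %in% gene_set
  nh <- sum(hit)
  n <- length(ranking)
  wsum <- sum(abs(ranking[hit])^p)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (wsum > 0) abs(ranking[i])^p / wsum else 1 / nh
    } else {
      -1 / (n - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # positive extreme wins a +/- tie, mirroring the stated convention
  as.numeric(if (abs(hi) >= abs(lo) - 1e-9) hi else lo)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled sample to the two groups.
enum_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Hypergeometric upper-tail probability from binomial coefficients.
hyper_tail <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) *
        choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# All simple paths between two nodes by depth-first search over an edge
# data.frame. Returns a list of character vectors.
all_simple_paths_df <- function(edges, from, to) {
  adj <- split(edges$to, edges$from)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (!(u %in% path)) walk(c(path, u))
    }
  }
  if (from %in% names(adj) || from == to) walk(from)
  out
}

path_key <- function(p) paste(p, collapse = ">")

# Lexicographic comparison of node sequences; TRUE if a < b.
lex_lt <- function(a, b) {
  key <- function(p) paste(p, collapse = "\r")
  key(a) < key(b)
}

# Exhaustive re-derivation of the curated-graph downstream search: all
# simple receptor->sink paths, keep per-pair the shortest (lex smallest
# on ties), filter by mean-fc score.
oracle_kegg <- function(receptors, fc, g, threshold) {
  outdeg <- table(factor(g$edges$from, levels = g$nodes))
  sinks <- g$nodes[outdeg == 0]
  kept <- list()
  for (r in intersect(receptors, g$nodes)) {
    for (t in setdiff(sinks, r)) {
      ps <- all_simple_paths_df(g$edges, r, t)
      if (!length(ps)) next
      lens <- vapply(ps, length, 1L)
      ps <- ps[lens == min(lens)]
      best <- ps[[1]]
      for (p in ps) if (lex_lt(p, best)) best <- p
      fcv <- fc[best]; fcv[is.na(fcv)] <- 0
      s <- mean(fcv)
      if (s > threshold) kept[[length(kept) + 1]] <- best
    }
  }
  sort(vapply(kept, path_key, ""))
}

# Step-by-step re-derivation of the greedy dense-graph search for one
# receptor, enumerating simple paths to find minimum-weight routes.
oracle_string_one <- function(receptor, fc, g, k1, k2, N, eps = 1e-6) {
  fcv <- stats::setNames(rep(0, length(g$nodes)), g$nodes)
  fcv[names(fc)[names(fc) %in% g$nodes]] <-
    fc[names(fc) %in% g$nodes]
  wt <- function(a, b) 1 / max(abs(fcv[[a]]), eps) +
    1 / max(abs(fcv[[b]]), eps)
  path_w <- function(p) {
    if (length(p) < 2) return(0)
    sum(vapply(seq_len(length(p) - 1),
               function(i) wt(p[i], p[i + 1]), 0))
  }
  net <- receptor
  trace <- list()
  repeat {
    if (length(net) >= N) break
    pool <- setdiff(g$nodes, net)
    if (!length(pool)) break
    cand <- pool[order(-abs(fcv[pool]), pool)][seq_len(min(k1, length(pool)))]
    best <- NULL
    for (gk in sort(net)) {
      for (cj in sort(cand)) {
        ps <- all_simple_paths_df(g$edges, gk, cj)
        if (!length(ps)) next
        ws <- vapply(ps, path_w, 0)
        minw <- min(ws)
        ps <- ps[abs(ws - minw) <= 1e-9 * max(1, minw)]
        sp <- ps[[1]]
        for (p in ps) if (lex_lt(p, sp)) sp <- p
        if (length(sp) > k2) next
        s <- mean(fcv[sp])
        if (is.null(best) || s > best$score + 1e-12 ||
            (abs(s - best$score) <= 1e-12 &&
             (length(sp) < length(best$nodes) ||
              (length(sp) == length(best$nodes) &&
               lex_lt(sp, best$nodes))))) {
          best <- list(nodes = sp, score = s)
        }
      }
    }
    if (is.null(best)) break
    trace[[length(trace) + 1]] <- best
    net <- union(net, best$nodes)
  }
  list(nodes = net, trace = trace)
}

# Random small DAG over a shuffled topological order.
random_dag <- function(n, seed, p_edge = 0.35) {
  set.seed(seed)
  nodes <- sprintf("N%02d", sample(n))
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge)
        edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[j],
                                         stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = nodes[1], to = nodes[2],
                        stringsAsFactors = FALSE)
  signaling_graph(edges, "kegg-like")
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Small deterministic expression fixture: k well-separated gaussian
# populations in gene space.
blob_matrix <- function(n_per = 40, k = 3, n_genes = 60, sep = 6,
                        seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, n_genes)
  block <- floor(n_genes / k)
  for (i in seq_len(k))
    centers[i, ((i - 1) * block + 1):(i * block)] <- sep
  x <- do.call(cbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_genes * n_per, mean = centers[i, ], sd = 0.5),
           n_genes, n_per)
  }))
  dimnames(x) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("C%03d", seq_len(ncol(x))))
  attr(x, "truth") <- rep(seq_len(k), each = n_per)
  x
}
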