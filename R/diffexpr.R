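# Two-test differential expression between conditions within a cell type,
# and Fisher-exact gene-set over-representation on the up-regulated genes.

#' Bimodal likelihood-ratio test for single-cell expression
#'
#' Each group is modeled as a mixture of a point mass at zero (dropout)
#' and a Gaussian over the nonzero values. The statistic is
#' `2 * (ll_x + ll_y - ll_pooled)` with all parameters at their (variance
#' floored) maximum-likelihood values, so it is nonnegative by nesting;
#' the p-value comes from a chi-square with 3 degrees of freedom (the
#' mixing weight, mean and variance are each freed per group).
#'
#' @param x,y numeric expression vectors for the two groups.
#' @param var_floor lower bound on the Gaussian variance (default 1e-6),
#'   guarding degenerate fits when a group has < 2 distinct nonzero
#'   values.
#' @return list with `statistic` and `p.value`; an all-zero pooled input
#'   returns `p = 1` by convention.
#' @export
bimod_lrt <- function(x, y, var_floor = 1e-6) {
  ll <- function(v) {
    n <- length(v)
    nz <- v[v != 0]
    n1 <- length(nz)
    p <- n1 / n
    out <- 0
    if (n1 > 0 && n1 < n) out <- n1 * log(p) + (n - n1) * log(1 - p)
    if (n1 > 0) {
      mu <- mean(nz)
      s2 <- max(sum((nz - mu)^2) / n1, var_floor) # MLE variance, floored
      out <- out + sum(stats::dnorm(nz, mu, sqrt(s2), log = TRUE))
    }
    out
  }
  if (all(c(x, y) == 0)) return(list(statistic = 0, p.value = 1))
  stat <- 2 * (ll(x) + ll(y) - ll(c(x, y)))
  stat <- max(stat, 0) # guard tiny negative rounding
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 3, lower.tail = FALSE))
}

#' Dual-test differential expression
#'
#' Per gene: log fold change = mean(test) - mean(control) on normalized
#' values; a Wilcoxon rank-sum p-value and a bimodal likelihood-ratio
#' p-value, each multiplicity-adjusted separately. A gene is flagged up
#' (`is_up`) when its fold change exceeds `fc_threshold` AND both adjusted
#' p-values fall below `p_threshold`.
#'
#' @param e normalized genes x cells matrix.
#' @param cells_test,cells_control disjoint barcode vectors (>= 2 cells
#'   each).
#' @param fc_threshold log-fold-change cut (default 0.08).
#' @param p_threshold adjusted p-value cut for both tests (default 0.05).
#' @param adjust multiple-testing method for the DE tests (default
#'   `"bonferroni"`; any `p.adjust` method).
#' @return data.frame of class `de_result`: gene, logFC, p_wilcoxon,
#'   p_lrt, adj_p_wilcoxon, adj_p_lrt, is_up.
#' @export
de_test <- function(e, cells_test, cells_control, fc_threshold = 0.08,
                    p_threshold = 0.05, adjust = "bonferroni") {
  if (length(intersect(cells_test, cells_control)))
    stop("test and control cell sets overlap")
  if (length(cells_test) < 2 || length(cells_control) < 2)
    stop("each group needs at least 2 cells")
  x <- as_dense(e)
  xt <- x[, cells_test, drop = FALSE]
  xc <- x[, cells_control, drop = FALSE]
  lfc <- rowMeans(xt) - rowMeans(xc)
  pw <- pl <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    a <- xt[g, ]; b <- xc[g, ]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
      pw[g] <- 1
      pl[g] <- 1
    } else {
      pw[g] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      pl[g] <- bimod_lrt(a, b)$p.value
    }
  }
  adj_w <- stats::p.adjust(pw, method = adjust)
  adj_l <- stats::p.adjust(pl, method = adjust)
  res <- data.frame(gene = rownames(x), logFC = unname(lfc),
                    p_wilcoxon = pw, p_lrt = pl,
                    adj_p_wilcoxon = adj_w, adj_p_lrt = adj_l,
                    is_up = unname(lfc > fc_threshold & adj_w < p_threshold &
                                     adj_l < p_threshold),
                    stringsAsFactors = FALSE)
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "p_threshold") <- p_threshold
  class(res) <- c("de_result", class(res))
  res
}

#' Named fold-change vector from a DE table
#' @param de `de_result` data.frame.
#' @return named numeric vector gene -> logFC.
#' @export
fc_map <- function(de) stats::setNames(de$logFC, de$gene)

#' Fisher-exact gene-set over-representation
#'
#' One-sided (enrichment) Fisher exact test per set from the 2x2 table of
#' query membership versus set membership inside the universe, i.e. the
#' hypergeometric tail probability of the observed or larger overlap;
#' Benjamini-Hochberg adjusted and sorted by p-value.
#'
#' @param query_genes character vector (e.g. up-regulated genes); clipped
#'   to the universe.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene symbols (e.g. all genes surviving QC).
#' @param adjust `p.adjust` method (default `"BH"`).
#' @return data.frame (set, overlap, set_size, query_size, p, adj_p).
#' @export
fisher_enrichment <- function(query_genes, sets, universe, adjust = "BH") {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  q <- intersect(unique(query_genes), universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(q, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(q), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(q), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = adjust)
  out[order(out$p, out$set), , drop = FALSE]
}
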