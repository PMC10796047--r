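# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up fold changes with a zero default
#'
#' Genes absent from a differential-expression table contribute a fold
#' change of 0 to all network scores.
#'
#' @param fc named numeric vector (gene -> logFC).
#' @param genes character vector of gene symbols.
#' @return numeric vector, one value per gene, 0 where missing.
#' @export
fc_lookup <- function(fc, genes) {
  out <- unname(fc[genes])
  out[is.na(out)] <- 0
  out
}

#' Jaccard overlap of two node sets
#'
#' @param a,b character vectors.
#' @return |a intersect b| / |a union b|; 1 if both empty.
#' @export
node_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

# Stop unless x is a gene x cell matrix with unique dimnames.
assert_counts <- function(m, what = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry gene rownames and cell barcode colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(m)[duplicated(rownames(m))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell barcodes: ",
         paste(unique(colnames(m)[duplicated(colnames(m))])[1:3], collapse = ", "))
  invisible(m)
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Dense numeric matrix from any matrix-like input.
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else as.matrix(m)
}
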