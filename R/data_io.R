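# Readers and writers for every external table/matrix format the pipeline
# touches, plus species symbol mapping. Matrices are genes x cells
# everywhere; MatrixMarket triplets are 1-based.

#' Read a gene-by-cell count matrix
#'
#' Supports MatrixMarket coordinate triplets with barcode/feature sidecar
#' files, and dense delimited text with gene symbols in the first column
#' and barcodes in the header.
#'
#' @param path path to the matrix file (`.mtx` for the triplet format).
#' @param format `"mtx"`, `"dense"`, or `"auto"` (by file extension).
#' @param barcodes,features sidecar paths for the triplet format; default
#'   `barcodes.tsv` / `features.tsv` next to `path`. Feature files may have
#'   one column (symbol) or several (id, symbol, ...); the symbol column
#'   (second if present) is used.
#' @param sep field separator for the dense format.
#' @param uppercase normalize gene symbols to uppercase (human convention);
#'   set `FALSE` for mouse data that still needs ortholog mapping.
#' @return sparse `Matrix::dgCMatrix`, genes x cells, nonnegative integers.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "dense"),
                        barcodes = NULL, features = NULL, sep = "\t",
                        uppercase = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket header in ",
                                           path, ": ", conditionMessage(e)))
    dir <- dirname(path)
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    features <- features %||% file.path(dir, "features.tsv")
    if (!file.exists(barcodes)) stop("barcode sidecar not found: ", barcodes)
    if (!file.exists(features)) stop("feature sidecar not found: ", features)
    bc <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    ft <- utils::read.table(features, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    sym <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    if (nrow(m) != length(sym))
      stop("feature sidecar has ", length(sym), " rows but matrix has ",
           nrow(m), " genes")
    if (ncol(m) != length(bc))
      stop("barcode sidecar has ", length(bc), " rows but matrix has ",
           ncol(m), " cells")
    dimnames(m) <- list(sym, bc)
  } else {
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("dense count file contains non-numeric entries")
  }
  if (uppercase) rownames(m) <- toupper(rownames(m))
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(m != round(m))) stop("non-integral counts in ", path)
  assert_counts(m)
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

#' Write a count matrix
#'
#' @param m genes x cells matrix.
#' @param path output `.mtx` (triplet, with `barcodes.tsv`/`features.tsv`
#'   sidecars) or delimited text file.
#' @param format see [read_counts()].
#' @export
write_counts <- function(m, path, format = c("auto", "mtx", "dense")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  assert_counts(m)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(as_dense(m), sparse = TRUE),
                                "CsparseMatrix"), path)
    dir <- dirname(path)
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
    writeLines(rownames(m), file.path(dir, "features.tsv"))
  } else {
    df <- data.frame(gene = rownames(m), as_dense(m), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Map gene symbols across species
#'
#' Renames genes by an ortholog map (e.g. mouse -> human). Source genes
#' absent from the map are dropped; several sources mapping to one
#' destination are summed so each cell's library-size contribution is
#' preserved.
#'
#' @param m genes x cells count matrix.
#' @param map named character vector, `names` = source symbols, values =
#'   destination symbols (case-insensitive on the source side).
#' @return count matrix over destination symbols (uppercased).
#' @export
map_orthologs <- function(m, map) {
  assert_counts(m)
  names(map) <- toupper(names(map))
  dest <- map[toupper(rownames(m))]
  keep <- !is.na(dest)
  if (!any(keep))
    stop("no gene symbol matched the ortholog map; check the species setting")
  mm <- as_dense(m)[keep, , drop = FALSE]
  grp <- toupper(unname(dest[keep]))
  out <- rowsum(mm, group = grp, reorder = TRUE)
  assert_counts(out, "mapped matrix")
  methods::as(methods::as(Matrix::Matrix(out, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then tab-separated gene symbols.
#'
#' @param path GMT file.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("GMT line without genes at line ", which(bad)[1])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

read_two_col <- function(path, cols, what) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(cols %in% names(df)))
    stop(what, " table must have columns: ", paste(cols, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  df
}

#' Read a ligand-receptor interaction table
#'
#' TSV with columns `ligand` and `receptor`; duplicate pairs collapse.
#'
#' @param path TSV file.
#' @return object of class `lr_db`: list with `ligands`, `receptors`,
#'   and `pairs` (data.frame ligand/receptor).
#' @export
read_lr_table <- function(path) {
  df <- read_two_col(path, c("ligand", "receptor"), "ligand-receptor")
  lr_db(toupper(df$ligand), toupper(df$receptor))
}

#' Construct a ligand-receptor database from paired vectors
#' @param ligand,receptor parallel character vectors of interacting pairs.
#' @return `lr_db` object.
#' @export
lr_db <- function(ligand, receptor) {
  pairs <- unique(data.frame(ligand = ligand, receptor = receptor,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(ligands = sort(unique(pairs$ligand)),
                 receptors = sort(unique(pairs$receptor)),
                 pairs = pairs),
            class = "lr_db")
}

#' @export
print.lr_db <- function(x, ...) {
  cat("ligand-receptor database:", length(x$ligands), "ligands,",
      length(x$receptors), "receptors,", nrow(x$pairs), "interactions\n")
  invisible(x)
}

#' Write a ligand-receptor table
#' @param db `lr_db` object.
#' @param path output TSV.
#' @export
write_lr_table <- function(db, path) {
  utils::write.table(db$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor/target table
#' @param path TSV with columns `tf` and `target`.
#' @return data.frame with unique (tf, target) pairs, uppercased.
#' @export
read_tf_table <- function(path) {
  df <- read_two_col(path, c("tf", "target"), "TF-target")
  unique(data.frame(tf = toupper(df$tf), target = toupper(df$target),
                    stringsAsFactors = FALSE))
}

#' Write a transcription-factor/target table
#' @param tf data.frame with columns `tf`, `target`.
#' @param path output TSV.
#' @export
write_tf_table <- function(tf, path) {
  utils::write.table(tf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-target table
#'
#' TSV with columns `drug`, `target` and optionally `smiles` (one SMILES
#' per drug; repeated rows must agree).
#'
#' @param path TSV file.
#' @return list with `targets` (named list drug -> target symbol set) and
#'   `smiles` (named character vector, possibly empty).
#' @export
read_drug_targets <- function(path) {
  df <- read_two_col(path, c("drug", "target"), "drug-target")
  targets <- lapply(split(toupper(df$target), df$drug), unique)
  smiles <- character(0)
  if ("smiles" %in% names(df)) {
    sm <- df$smiles[!is.na(df$smiles) & nzchar(df$smiles)]
    nm <- df$drug[!is.na(df$smiles) & nzchar(df$smiles)]
    smiles <- tapply(sm, nm, function(v) {
      u <- unique(v)
      if (length(u) > 1) stop("conflicting SMILES for one drug")
      u
    })
    smiles <- stats::setNames(as.character(smiles), names(smiles))
  }
  list(targets = targets, smiles = smiles)
}

#' Write a drug-target table
#' @param dt list as returned by [read_drug_targets()].
#' @param path output TSV.
#' @export
write_drug_targets <- function(dt, path) {
  rows <- do.call(rbind, lapply(names(dt$targets), function(d) {
    data.frame(drug = d, target = dt$targets[[d]],
               smiles = if (d %in% names(dt$smiles)) dt$smiles[[d]] else "",
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell design table
#'
#' TSV with columns `cell`, `sample`, `group`. Every barcode maps to
#' exactly one sample.
#'
#' @param path TSV file.
#' @return data.frame (cell, sample, group).
#' @export
read_design <- function(path) {
  df <- read_two_col(path, c("cell", "sample", "group"), "design")
  if (anyDuplicated(df$cell))
    stop("design table maps a barcode to more than one sample: ",
         df$cell[duplicated(df$cell)][1])
  df[c("cell", "sample", "group")]
}

#' Write a cell design table
#' @param design data.frame (cell, sample, group).
#' @param path output TSV.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker-gene table
#' @param path TSV with columns `cell_type` and `gene`.
#' @return data.frame of unique (cell_type, gene) rows; cell-type order of
#'   first appearance is preserved (it breaks annotation ties).
#' @export
read_marker_table <- function(path) {
  df <- read_two_col(path, c("cell_type", "gene"), "marker")
  unique(data.frame(cell_type = df$cell_type, gene = toupper(df$gene),
                    stringsAsFactors = FALSE))
}

#' Write a marker-gene table
#' @param markers data.frame (cell_type, gene).
#' @param path output TSV.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Add a (cell type, gene) row to a marker table
#' @param markers data.frame (cell_type, gene).
#' @param cell_type,gene row to add; a duplicate row is a no-op.
#' @return updated marker table.
#' @export
marker_add <- function(markers, cell_type, gene) {
  unique(rbind(markers,
               data.frame(cell_type = cell_type, gene = toupper(gene),
                          stringsAsFactors = FALSE)))
}

#' Delete a (cell type, gene) row from a marker table
#' @inheritParams marker_add
#' @return updated marker table.
#' @export
marker_delete <- function(markers, cell_type, gene) {
  keep <- !(markers$cell_type == cell_type & markers$gene == toupper(gene))
  markers[keep, , drop = FALSE]
}

#' Read an ortholog map
#' @param path TSV with columns `source` and `dest`.
#' @return named character vector (source symbol -> destination symbol).
#' @export
read_ortholog_map <- function(path) {
  df <- read_two_col(path, c("source", "dest"), "ortholog")
  if (anyDuplicated(df$source))
    stop("ortholog map is not a function: duplicated source ",
         df$source[duplicated(df$source)][1])
  stats::setNames(df$dest, df$source)
}

#' Write an ortholog map
#' @param map named character vector (source -> dest).
#' @param path output TSV.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(data.frame(source = names(map), dest = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed signaling graph from an edge list
#'
#' @param path TSV with columns `from`, `to` and optionally `pathway`.
#' @param source_tag `"kegg-like"` (curated pathway union) or
#'   `"string-like"` (dense interactome).
#' @return `signaling_graph` object (see [signaling_graph()]).
#' @export
read_signaling_graph <- function(path, source_tag = c("kegg-like",
                                                      "string-like")) {
  df <- read_two_col(path, c("from", "to"), "signaling edge")
  signaling_graph(df, match.arg(source_tag))
}

#' Construct a directed signaling graph
#'
#' Self-loops are dropped and duplicate edges collapsed; per-pathway
#' subgraphs are merged on gene symbol so inter-pathway crosstalk is kept.
#'
#' @param edges data.frame with columns `from`, `to` (and optionally
#'   `pathway`).
#' @param source_tag `"kegg-like"` or `"string-like"`.
#' @return list of class `signaling_graph` with `edges`, `nodes`,
#'   `source_tag`.
#' @export
signaling_graph <- function(edges, source_tag = "kegg-like") {
  edges$from <- toupper(edges$from)
  edges$to <- toupper(edges$to)
  edges <- unique(edges[edges$from != edges$to, c("from", "to"), drop = FALSE])
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$from, edges$to))),
                 source_tag = source_tag),
            class = "signaling_graph")
}

#' @export
print.signaling_graph <- function(x, ...) {
  cat("signaling graph (", x$source_tag, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Write a signaling graph edge list
#' @param g `signaling_graph`.
#' @param path output TSV.
#' @export
write_signaling_graph <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug rank matrix
#'
#' Genes in rows (first column), drugs in columns. Every drug column must
#' be a permutation of 1..n_genes (rank 1 = most up-regulated gene).
#'
#' @param path TSV file.
#' @return integer matrix genes x drugs.
#' @export
read_drug_rank_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- toupper(rownames(m))
  validate_rank_matrix(m)
  m
}

validate_rank_matrix <- function(m) {
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (!identical(sort(as.integer(m[, j])), seq_len(n)))
      stop("drug rank column '", colnames(m)[j],
           "' is not a permutation of 1..", n)
  }
  invisible(m)
}

#' Write a drug rank matrix
#' @param m integer matrix genes x drugs.
#' @param path output TSV.
#' @export
write_drug_rank_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
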