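#' @importFrom Matrix Matrix colSums rowSums rowMeans t readMM writeMM sparseMatrix
#' @importFrom stats cor dist kmeans median p.adjust pchisq pnorm prcomp pt
#'   quantile rbeta rbinom rexp rlnorm rnbinom rnorm runif sd var setNames
#'   chisq.test kruskal.test wilcox.test
#' @importFrom utils head read.delim write.csv write.table packageVersion
NULL

#' Single-cell count matrix with sample assignments
#'
#' A light container for multi-sample UMI count data: a sparse integer matrix
#' (genes in rows, cells in columns) plus the mapping of every cell to the
#' sample it was profiled from. Gene symbols and cell ids are carried as
#' dimnames and must be unique.
#'
#' @param counts matrix or `Matrix::dgCMatrix` of nonnegative integer counts,
#'   genes x cells, with unique rownames (gene symbols) and colnames (cell ids).
#' @param sample_of_cell character vector, one sample id per cell, in column
#'   order (or named by cell id).
#' @return An object of class `tam_counts`.
#' @export
tam_counts <- function(counts, sample_of_cell) {
  counts <- methods::as(methods::as(Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry gene symbols as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("negative counts")
  if (length(sample_of_cell) != ncol(counts))
    stop("sample_of_cell must have one entry per cell")
  if (!is.null(names(sample_of_cell)))
    sample_of_cell <- sample_of_cell[colnames(counts)]
  names(sample_of_cell) <- colnames(counts)
  structure(list(counts = counts, sample_of_cell = sample_of_cell),
            class = "tam_counts")
}

#' Normalized expression matrix
#'
#' Holds log2(1 + TPK) expression values on the same genes x cells layout as
#' [tam_counts()]. Entries are zero exactly where the raw count was zero, so
#' the matrix stays sparse.
#'
#' @param values sparse or dense numeric matrix, genes x cells, nonnegative.
#' @param sample_of_cell per-cell sample ids (see [tam_counts()]).
#' @return An object of class `tam_norm`.
#' @export
tam_norm <- function(values, sample_of_cell) {
  values <- methods::as(methods::as(Matrix(values, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(values@x < 0)) stop("normalized values must be nonnegative")
  if (!is.null(names(sample_of_cell)))
    sample_of_cell <- sample_of_cell[colnames(values)]
  names(sample_of_cell) <- colnames(values)
  structure(list(values = values, sample_of_cell = sample_of_cell),
            class = "tam_norm")
}

#' @export
print.tam_counts <- function(x, ...) {
  cat(sprintf("tam_counts: %d genes x %d cells, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_of_cell))))
  invisible(x)
}

#' @export
print.tam_norm <- function(x, ...) {
  cat(sprintf("tam_norm (log2(1+TPK)): %d genes x %d cells, %d samples\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_of_cell))))
  invisible(x)
}

#' @export
dim.tam_counts <- function(x) dim(x$counts)
#' @export
dim.tam_norm <- function(x) dim(x$values)

#' Gene symbols of a matrix container
#' @param x a `tam_counts` or `tam_norm` object.
#' @return character vector of gene symbols.
#' @export
gene_symbols <- function(x) UseMethod("gene_symbols")
#' @export
gene_symbols.tam_counts <- function(x) rownames(x$counts)
#' @export
gene_symbols.tam_norm <- function(x) rownames(x$values)

#' Cell ids of a matrix container
#' @param x a `tam_counts` or `tam_norm` object.
#' @return character vector of cell ids.
#' @export
cell_ids <- function(x) UseMethod("cell_ids")
#' @export
cell_ids.tam_counts <- function(x) colnames(x$counts)
#' @export
cell_ids.tam_norm <- function(x) colnames(x$values)

#' Subset a normalized matrix by cells and/or genes
#'
#' @param x a `tam_norm` object.
#' @param cells cell ids or logical/integer index over columns (optional).
#' @param genes gene symbols or index over rows (optional).
#' @return a `tam_norm` on the selected subset.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "tam_norm"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  tam_norm(v, x$sample_of_cell[colnames(v)])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment shared by all modules; a thin validated wrapper over
#' `p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Gene-symbol alias table
#'
#' Resolves common protein-name aliases (MCP-1, SDF-1, Ki-67, ...) to HGNC
#' gene symbols. The shipped table can be extended by the user.
#'
#' @param path optional path to a two-column TSV (alias, symbol); defaults to
#'   the table shipped with the package.
#' @return named character vector mapping alias to symbol.
#' @export
gene_aliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_aliases.tsv", package = "gliotam")
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(tab$symbol, tab$alias)
}

#' Apply the alias map to a vector of symbols
#' @param symbols character vector possibly containing aliases.
#' @param aliases named map as returned by [gene_aliases()].
#' @return symbols with aliases replaced.
#' @export
resolve_aliases <- function(symbols, aliases = gene_aliases()) {
  hit <- symbols %in% names(aliases)
  symbols[hit] <- unname(aliases[symbols[hit]])
  symbols
}
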