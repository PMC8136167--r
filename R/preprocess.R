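# Cohort preprocessing: mitochondrial/ribosomal filtering, multi-sample
# merging on the gene intersection, log2(1+TPK) normalization, and
# restriction to an immune gene panel.

MITO_RIBO_PATTERN <- "^(MT-|MRPL|MRPS|RPL|RPS)"

#' A named gene panel
#'
#' @param name panel name.
#' @param symbols unique character vector of gene symbols.
#' @return a `gene_panel` list.
#' @export
gene_panel <- function(name, symbols) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("panel symbols must be unique")
  structure(list(name = name, symbols = symbols), class = "gene_panel")
}

#' Read a gene panel from a one-symbol-per-line text file
#'
#' Blank lines and `#` comments are ignored; aliases are resolved through
#' the shipped alias table.
#'
#' @param path file path.
#' @param name panel name (defaults to the file name).
#' @return a [gene_panel()].
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(name, unique(resolve_aliases(lines)))
}

#' Remove mitochondrial and ribosomal protein genes
#'
#' Drops genes whose symbols match the community prefix convention
#' `MT-`, `MRPL`, `MRPS`, `RPL`, `RPS` (case-insensitive). Cells are
#' untouched.
#'
#' @param m a [tam_counts()].
#' @return a [tam_counts()] on the retained genes; warns if none remain.
#' @export
filter_mito_ribo <- function(m) {
  stopifnot(inherits(m, "tam_counts"))
  drop <- grepl(MITO_RIBO_PATTERN, gene_symbols(m), ignore.case = TRUE)
  if (all(drop)) warning("all genes matched the mito/ribo rule; empty matrix")
  out <- m$counts[!drop, , drop = FALSE]
  tam_counts(out, m$sample_of_cell)
}

#' Merge per-sample count matrices on their gene intersection
#'
#' Keeps the intersection of the input gene sets (in the order of the first
#' input), concatenates cells in input order, and discards genes with zero
#' total count in the merged matrix.
#'
#' @param matrices list of [tam_counts()] with disjoint cell ids.
#' @return a merged [tam_counts()].
#' @export
merge_cohort <- function(matrices) {
  if (length(matrices) < 1) stop("need at least one matrix")
  stopifnot(all(vapply(matrices, inherits, logical(1), "tam_counts")))
  ids <- unlist(lapply(matrices, cell_ids))
  if (anyDuplicated(ids)) stop("duplicate cell ids across inputs")
  common <- Reduce(intersect, lapply(matrices, gene_symbols))
  if (length(common) == 0) stop("empty gene intersection across inputs")
  merged <- do.call(cbind, lapply(matrices,
                                  function(m) m$counts[common, , drop = FALSE]))
  keep <- rowSums(merged) > 0
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) stop("no gene has nonzero total count after merging")
  samples <- unlist(lapply(matrices, function(m) m$sample_of_cell))
  tam_counts(merged, setNames(unname(samples), ids))
}

#' Normalize UMI counts to log2(1 + TPK)
#'
#' TPK (transcripts per thousand) rescales each cell's counts to sum to
#' 1000; values are then log2(1 + TPK). Zero counts map to exactly zero, so
#' sparsity is preserved.
#'
#' @param m a [tam_counts()]; every cell must have total count > 0.
#' @return a [tam_norm()].
#' @export
normalize_tpk <- function(m) {
  stopifnot(inherits(m, "tam_counts"))
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(head(cell_ids(m)[totals == 0], 5), collapse = ", "))
  x <- m$counts
  # column-scale the sparse matrix in place: x@x are nonzeros, column-major
  scale_per_col <- 1000 / totals
  x@x <- log2(1 + x@x * rep.int(scale_per_col, diff(x@p)))
  tam_norm(x, m$sample_of_cell)
}

#' Restrict a normalized matrix to a gene panel
#'
#' Keeps the intersection of the matrix genes with the panel, in matrix
#' order, and reports the intersection size as an attribute
#' (`panel_overlap`) and a message.
#'
#' @param m a [tam_norm()].
#' @param panel a [gene_panel()].
#' @param quiet suppress the intersection-size message.
#' @return a [tam_norm()] on the intersection.
#' @export
restrict_to_panel <- function(m, panel, quiet = FALSE) {
  stopifnot(inherits(m, "tam_norm"), inherits(panel, "gene_panel"))
  keep <- intersect(gene_symbols(m), panel$symbols)
  if (length(keep) == 0) stop("no matrix gene overlaps panel '", panel$name, "'")
  if (!quiet)
    message(sprintf("panel '%s': %d of %d matrix genes retained",
                    panel$name, length(keep), nrow(m$values)))
  out <- tam_norm(m$values[keep, , drop = FALSE], m$sample_of_cell)
  attr(out, "panel_overlap") <- length(keep)
  out
}

#' Read a cohort from Matrix Market + sidecar files
#'
#' Expects `matrix.mtx` (genes x cells), `genes.tsv` (one symbol per line,
#' or first column of a TSV) and `barcodes.tsv` (barcode, optionally a
#' second sample column). If no sample column is present every cell is
#' assigned to `sample`.
#'
#' @param dir directory with the three files.
#' @param sample fallback sample id.
#' @return a [tam_counts()].
#' @export
read_cohort_mtx <- function(dir, sample = basename(dir)) {
  counts <- methods::as(readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bc <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                   stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- bc[[1]]
  samples <- if (ncol(bc) >= 2) bc[[2]] else rep(sample, nrow(bc))
  tam_counts(counts, setNames(samples, bc[[1]]))
}

#' Read a dense TSV count matrix
#'
#' @param path TSV with gene symbols in the first column and cells in the
#'   remaining columns (`orientation = "genes_in_rows"`), or transposed
#'   (`"cells_in_rows"`).
#' @param sample sample id assigned to every cell (or vector per cell).
#' @param orientation matrix layout flag.
#' @return a [tam_counts()].
#' @export
read_counts_tsv <- function(path, sample = basename(path),
                            orientation = c("genes_in_rows",
                                            "cells_in_rows")) {
  orientation <- match.arg(orientation)
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (orientation == "cells_in_rows") m <- t(m)
  if (length(sample) == 1) sample <- rep(sample, ncol(m))
  tam_counts(m, setNames(sample, colnames(m)))
}

#' Write a normalized matrix as TSV
#'
#' @param m a [tam_norm()].
#' @param path output path (genes x cells, dense TSV).
#' @return `path`, invisibly.
#' @export
write_norm_tsv <- function(m, path) {
  stopifnot(inherits(m, "tam_norm"))
  write.table(as.matrix(m$values), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Standard preprocessing of a list of per-sample matrices
#'
#' Applies, in order: mito/ribo filtering per input, merging on the gene
#' intersection (dropping zero-total genes), log2(1+TPK) normalization on
#' all retained genes, then panel restriction. Normalization precedes panel
#' restriction so per-cell totals use the full retained gene set.
#'
#' @param matrices list of [tam_counts()] (one is fine).
#' @param panel a [gene_panel()] or NULL to skip restriction.
#' @param quiet suppress progress messages.
#' @return list: `normalized` (a [tam_norm()]), `provenance` (gene counts
#'   before/after each step).
#' @export
preprocess_cohort <- function(matrices, panel = NULL, quiet = TRUE) {
  if (inherits(matrices, "tam_counts")) matrices <- list(matrices)
  n0 <- vapply(matrices, function(m) nrow(m$counts), integer(1))
  filtered <- lapply(matrices, filter_mito_ribo)
  merged <- merge_cohort(filtered)
  norm <- normalize_tpk(merged)
  prov <- list(genes_in = n0,
               genes_after_mito_ribo = vapply(filtered, function(m)
                 nrow(m$counts), integer(1)),
               genes_after_merge = nrow(merged$counts))
  if (!is.null(panel)) {
    norm <- restrict_to_panel(norm, panel, quiet = quiet)
    prov$genes_after_panel <- attr(norm, "panel_overlap")
  }
  list(normalized = norm, provenance = prov)
}
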