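# Per-cell gene-set signature scores (expression-subtype, BMDM vs microglia,
# recruitment-factor cross-talk) and paired macrophage-tumor correlations.

#' The tumor-macrophage recruitment-factor panel
#'
#' The 12 HGNC symbols of the 10-factor macrophage recruitment program
#' (TGF-beta expands to TGFB1/2/3): CSF1, CSF2, HGF, CCL2 (MCP-1), MIF,
#' CXCL12 (SDF-1), TGFB1, TGFB2, TGFB3, IL10, SPP1, MFGE8.
#'
#' @return a [gene_panel()] of the 12 symbols.
#' @export
crosstalk_panel <- function() {
  gene_panel("recruitment_factors",
             c("CSF1", "CSF2", "HGF", "CCL2", "MIF", "CXCL12",
               "TGFB1", "TGFB2", "TGFB3", "IL10", "SPP1", "MFGE8"))
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member symbols. Aliases
#' are resolved through the shipped alias table.
#'
#' @param path GMT file path.
#' @return named list of unique symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(resolve_aliases(parts[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Per-cell signature score of a gene set
#'
#' The single-cell relative-expression score: each set gene's normalized
#' expression is centered across the scored cell population, and a cell's
#' score is the mean of the centered values over the set genes present in
#' the matrix. Scores therefore have mean (numerically) zero over the
#' scored cells, and set genes absent from the matrix are dropped with a
#' message.
#'
#' @param m a [tam_norm()].
#' @param cells cell ids (or index) defining the scored population; NULL
#'   scores all cells.
#' @param set character vector of gene symbols, or a [gene_panel()].
#' @param quiet suppress the dropped-gene message.
#' @return named numeric vector of per-cell scores over the scored cells.
#' @export
signature_score <- function(m, cells = NULL, set, quiet = TRUE) {
  stopifnot(inherits(m, "tam_norm"))
  if (inherits(set, "gene_panel")) set <- set$symbols
  if (!is.null(cells)) m <- subset_cells(m, cells = cells)
  present <- intersect(set, gene_symbols(m))
  if (length(present) == 0) stop("no set gene present in the matrix")
  if (!quiet && length(present) < length(set))
    message(sprintf("%d of %d set genes absent from matrix; dropped",
                    length(set) - length(present), length(set)))
  v <- as.matrix(m$values[present, , drop = FALSE])
  centered <- v - rowMeans(v)
  setNames(colMeans(centered), cell_ids(m))
}

#' Per-sample mean signature score of a compartment
#'
#' @param scores per-cell scores from [signature_score()].
#' @param annotation data.frame with cell_id, sample, cell_type.
#' @param compartment cell type to summarize.
#' @return named numeric vector, one mean score per sample with >= 1 cell of
#'   the compartment.
#' @export
sample_compartment_means <- function(scores, annotation, compartment) {
  ann <- annotation[annotation$cell_type == compartment &
                      annotation$cell_id %in% names(scores), ]
  if (nrow(ann) == 0) stop("no scored cell in compartment ", compartment)
  tapply(scores[ann$cell_id], ann$sample, mean)
}

#' Compare per-sample signature scores between two cell compartments
#'
#' For each signature, cells of both compartments are scored together,
#' per-sample compartment means are formed, and a two-sided Mann-Whitney U
#' test compares the paired sample populations. Samples missing a
#' compartment are excluded from that comparison (with a warning). BH
#' adjustment is applied across signatures.
#'
#' @param m a [tam_norm()].
#' @param annotation data.frame with cell_id, sample, cell_type.
#' @param sets named list of gene sets.
#' @param compartments length-2 character, e.g. c("macrophage", "tumor").
#' @return data.frame: signature, U, p_value, adj_p, n_samples,
#'   mean_first, mean_second (per-compartment means of sample means).
#' @export
compartment_score_compare <- function(m, annotation, sets,
                                      compartments = c("macrophage",
                                                       "tumor")) {
  stopifnot(length(compartments) == 2)
  ann <- annotation[annotation$cell_type %in% compartments, ]
  if (any(!compartments %in% ann$cell_type))
    stop("compartment with no cells: ",
         paste(setdiff(compartments, ann$cell_type), collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    sc <- signature_score(m, cells = ann$cell_id, set = sets[[nm]])
    m1 <- sample_compartment_means(sc, ann, compartments[1])
    m2 <- sample_compartment_means(sc, ann, compartments[2])
    common <- intersect(names(m1), names(m2))
    if (length(common) < length(union(names(m1), names(m2))))
      warning(sprintf("signature %s: %d sample(s) missing a compartment",
                      nm, length(union(names(m1), names(m2))) -
                        length(common)))
    cmp <- group_mean_compare(m1[common], m2[common])
    data.frame(signature = nm, U = cmp$U, p_value = cmp$p_value,
               n_samples = length(common),
               mean_first = mean(m1[common]), mean_second = mean(m2[common]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_fdr(out$p_value)
  out
}

#' Spearman correlation with exact small-sample p-value
#'
#' Two-sided p by exhaustive enumeration of all rank permutations for
#' n <= 8 (exact under no ties), and by the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return list: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 pairs")
  rho <- cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    rx <- rank(x)
    perms <- .permutations(n)
    null_rho <- apply(perms, 1, function(p) cor(rx, p))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Paired macrophage-tumor cross-talk correlation
#'
#' Per sample: the mean normalized expression of a query gene (MARCO by
#' default) over that sample's macrophages, and the mean signature score of
#' a gene set (the recruitment-factor panel by default, or any expression
#' subtype signature) over that sample's tumor cells. The two per-sample
#' summaries are compared by Spearman correlation across samples; the tumor
#' signature is centered across all tumor cells of the valid samples.
#'
#' @param m a [tam_norm()] over the full cohort.
#' @param annotation data.frame with cell_id, sample, cell_type.
#' @param query_gene macrophage-side gene symbol.
#' @param set tumor-side gene set (symbols or [gene_panel()]).
#' @param min_samples minimum number of valid samples (default 4).
#' @return list: `rho`, `p_value`, `n`, `per_sample` (data.frame sample,
#'   macrophage_mean, tumor_score).
#' @export
paired_crosstalk_correlation <- function(m, annotation,
                                         query_gene = "MARCO",
                                         set = crosstalk_panel(),
                                         min_samples = 4) {
  stopifnot(inherits(m, "tam_norm"))
  if (!query_gene %in% gene_symbols(m))
    stop("query gene ", query_gene, " absent from matrix")
  macs <- annotation[annotation$cell_type == "macrophage", ]
  tums <- annotation[annotation$cell_type == "tumor", ]
  valid <- intersect(unique(macs$sample), unique(tums$sample))
  if (length(valid) < min_samples)
    stop("need >= ", min_samples,
         " samples with both macrophages and tumor cells")
  macs <- macs[macs$sample %in% valid, ]
  tums <- tums[tums$sample %in% valid, ]

  q <- as.numeric(m$values[query_gene, macs$cell_id])
  mac_mean <- tapply(q, macs$sample, mean)

  ts <- signature_score(m, cells = tums$cell_id, set = set)
  tum_score <- tapply(ts[tums$cell_id], tums$sample, mean)

  per_sample <- data.frame(sample = valid,
                           macrophage_mean = as.numeric(mac_mean[valid]),
                           tumor_score = as.numeric(tum_score[valid]),
                           stringsAsFactors = FALSE)
  st <- spearman_test(per_sample$macrophage_mean, per_sample$tumor_score)
  c(st[c("rho", "p_value", "n")], list(per_sample = per_sample))
}

#' BMDM-vs-microglia lineage contrast of macrophage subpopulations
#'
#' Scores both lineage sets over all macrophages, forms per
#' (sample x cluster) subpopulation means of the contrast (BMDM score minus
#' microglia score), and compares scavenger-cluster subpopulations against
#' the rest with a two-sided Mann-Whitney U test.
#'
#' @param m a [tam_norm()] over the macrophage compartment.
#' @param labels cluster labels per macrophage (named by cell id).
#' @param scavenger_cluster label of the scavenger (MARCO-like) cluster.
#' @param bmdm_set,microglia_set lineage gene sets.
#' @param min_subpops minimum total subpopulations required (default 4).
#' @return list: `per_subpop` (data.frame sample, cluster, contrast,
#'   is_scavenger), `U`, `p_value`, `n_subpops`.
#' @export
bmdm_microglia_contrast <- function(m, labels, scavenger_cluster,
                                    bmdm_set, microglia_set,
                                    min_subpops = 4) {
  stopifnot(inherits(m, "tam_norm"))
  if (!is.null(names(labels))) labels <- labels[cell_ids(m)]
  sb <- signature_score(m, set = bmdm_set)
  sm <- signature_score(m, set = microglia_set)
  contrast <- sb - sm
  key <- paste(m$sample_of_cell, labels, sep = "|")
  per <- tapply(contrast, key, mean)
  parts <- strsplit(names(per), "|", fixed = TRUE)
  per_subpop <- data.frame(
    sample = vapply(parts, `[`, character(1), 1),
    cluster = vapply(parts, `[`, character(1), 2),
    contrast = as.numeric(per),
    stringsAsFactors = FALSE)
  per_subpop$is_scavenger <-
    per_subpop$cluster == as.character(scavenger_cluster)
  if (nrow(per_subpop) < min_subpops)
    stop("only ", nrow(per_subpop), " subpopulations; need >= ", min_subpops)
  cmp <- group_mean_compare(per_subpop$contrast[per_subpop$is_scavenger],
                            per_subpop$contrast[!per_subpop$is_scavenger])
  list(per_subpop = per_subpop, U = cmp$U, p_value = cmp$p_value,
       n_subpops = nrow(per_subpop))
}
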