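# Marker statistics for the macrophage clusters: enrichment ranking with
# empirical exact-permutation p-values, leave-one-out robustness, nonzero
# fraction and group-level tests, and normalized-dispersion marker utility.

#' Cluster enrichment statistic
#'
#' For each gene, the mean normalized expression in the target cluster minus
#' the mean over all other cells in the matrix.
#'
#' @param m a [tam_norm()] restricted to the analysis panel over the
#'   macrophage compartment.
#' @param labels integer cluster labels, one per cell (named or in column
#'   order).
#' @param target_cluster label of the cluster being characterized.
#' @return named numeric vector of per-gene statistics.
#' @export
enrichment_statistic <- function(m, labels, target_cluster) {
  stopifnot(inherits(m, "tam_norm"))
  if (!is.null(names(labels))) labels <- labels[cell_ids(m)]
  inside <- labels == target_cluster
  if (!any(inside)) stop("target cluster is empty")
  if (all(inside)) stop("target cluster covers every cell")
  rowMeans(m$values[, inside, drop = FALSE]) -
    rowMeans(m$values[, !inside, drop = FALSE])
}

#' Empirical exact permutation p-values over a gene panel
#'
#' Treats the panel-wide distribution of the enrichment statistic as the
#' null: each gene's two-sided p is `2 * min(r_hi, r_lo) / n` where `r_hi`
#' (`r_lo`) counts the panel genes with statistic greater-or-equal
#' (less-or-equal) to the gene's, the gene itself included, capped at 1.
#' Ties therefore share the more conservative (larger) p. With 499 distinct
#' statistics the top-ranked gene receives p = 2/499 (0.004) and the
#' second-ranked p = 4/499 (0.008).
#'
#' @param statistics named numeric vector of per-gene statistics (n >= 2).
#' @return data.frame (`marker_result`): gene, statistic, rank (1-based,
#'   descending statistic), perm_p, adj_p (BH across the panel), sorted by
#'   rank.
#' @export
empirical_perm_p <- function(statistics) {
  if (length(statistics) < 2) stop("need at least 2 statistics")
  bad <- !is.finite(statistics)
  if (any(bad))
    stop("non-finite statistic for: ",
         paste(head(names(statistics)[bad], 5), collapse = ", "))
  n <- length(statistics)
  if (is.null(names(statistics)))
    names(statistics) <- sprintf("g%d", seq_len(n))
  r_lo <- rank(statistics, ties.method = "max")        # #{<= s}, self incl.
  r_hi <- n + 1 - rank(statistics, ties.method = "min") # #{>= s}, self incl.
  perm_p <- pmin(1, 2 * pmin(r_hi, r_lo) / n)
  res <- data.frame(gene = names(statistics),
                    statistic = unname(statistics),
                    rank = rank(-statistics, ties.method = "first"),
                    perm_p = unname(perm_p),
                    adj_p = unname(adjust_fdr(perm_p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  class(res) <- c("marker_result", "data.frame")
  res
}

#' Marker table for one macrophage cluster
#'
#' [enrichment_statistic()] followed by [empirical_perm_p()].
#'
#' @inheritParams enrichment_statistic
#' @return a `marker_result` data.frame (see [empirical_perm_p()]).
#' @export
marker_table <- function(m, labels, target_cluster) {
  empirical_perm_p(enrichment_statistic(m, labels, target_cluster))
}

#' Leave-one-out robustness of a marker gene's rank
#'
#' Re-runs the PCA -> UMAP -> k-means stage on the panel with the query gene
#' excluded, then recomputes the enrichment ranking on the full panel
#' (query included) against the new clustering, and reports the query's rank
#' and permutation p in the cluster where it is most enriched.
#'
#' @param m a [tam_norm()] over the macrophage compartment (panel genes).
#' @param gene query gene symbol.
#' @param cfg an [embedding_config()].
#' @return list: `rank`, `perm_p`, `k` (selected cluster count), `labels`,
#'   `target_cluster`.
#' @export
leave_one_out_rank <- function(m, gene, cfg = embedding_config()) {
  stopifnot(inherits(m, "tam_norm"))
  if (!gene %in% gene_symbols(m)) stop("gene ", gene, " absent from matrix")
  rest <- setdiff(gene_symbols(m), gene)
  if (length(rest) < 2)
    stop("cannot re-embed on fewer than 2 genes after excluding ", gene)
  reduced <- subset_cells(m, genes = rest)
  emb <- embed_cohort(reduced, cfg, type_cells = FALSE)
  cl <- cluster_macrophages(emb$coords, cfg)
  # characterize the cluster where the query is most enriched
  stats_by_cluster <- vapply(sort(unique(cl$labels)), function(ci)
    enrichment_statistic(m, cl$labels, ci)[gene], numeric(1))
  target <- sort(unique(cl$labels))[which.max(stats_by_cluster)]
  tab <- marker_table(m, cl$labels, target)
  row <- tab[tab$gene == gene, ]
  list(rank = row$rank, perm_p = row$perm_p, k = cl$k,
       labels = cl$labels, target_cluster = target)
}

#' Chi-squared test on nonzero-expression fractions of two cell groups
#'
#' Builds the 2x2 table of (nonzero, zero) x group and applies Pearson's
#' chi-squared test without continuity correction (1 df).
#'
#' @param groupA,groupB numeric expression vectors (one value per cell).
#' @return list (`contingency_result`): `table` (2x2, rows = groups,
#'   cols = nonzero/zero), `statistic`, `p_value`, `fractions` (per-group
#'   nonzero fraction).
#' @export
nonzero_fraction_test <- function(groupA, groupB) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be nonempty")
  tab <- rbind(A = c(nonzero = sum(groupA != 0), zero = sum(groupA == 0)),
               B = c(nonzero = sum(groupB != 0), zero = sum(groupB == 0)))
  contingency_chisq(tab)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param tab 2x2 nonnegative integer matrix.
#' @return list (`contingency_result`): `table`, `statistic`, `p_value`,
#'   `fractions` (first-column proportion per row).
#' @export
contingency_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("test undefined: a margin of the table is all zero")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 fractions = tab[, 1] / rowSums(tab)),
            class = "contingency_result")
}

#' Compare per-patient mean expression between two groups
#'
#' Two-sided Mann-Whitney U on patient-level means. For small groups
#' (up to 20 per group and at most 2e5 group assignments) the p-value is
#' exact, by enumeration of every assignment of the pooled values to the
#' two groups — which handles ties exactly; larger problems use the normal
#' approximation with tie correction. The fold ratio is the ratio of group
#' means, `Inf` when the reference group's mean is 0.
#'
#' @param groupA,groupB numeric vectors of per-patient means.
#' @return list: `U` (statistic for groupA), `p_value`, `fold_ratio`
#'   (mean(groupA)/mean(groupB)), `n` (per-group sizes), `method`.
#' @export
group_mean_compare <- function(groupA, groupB) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be nonempty")
  n1 <- length(groupA); n2 <- length(groupB)
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  small <- n1 <= 20 && n2 <= 20 && choose(n1 + n2, n1) <= 2e5
  if (small) {
    idx <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_null <= u_obs + eps),
                        mean(u_null >= u_obs - eps)))
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(
      wilcox.test(groupA, groupB, alternative = "two.sided",
                  exact = FALSE, correct = FALSE))
    p <- wt$p.value
    method <- "normal approximation"
  }
  fold <- if (mean(groupB) == 0) {
    if (mean(groupA) == 0) NaN else Inf
  } else mean(groupA) / mean(groupB)
  list(U = unname(u_obs), p_value = p, fold_ratio = fold,
       n = c(n1, n2), method = method)
}

#' Kruskal-Wallis comparison of expression across three or more groups
#'
#' @param groups list of >= 3 nonempty numeric vectors (e.g. expression by
#'   anatomic structure).
#' @return list: `H` (tie-corrected statistic), `p_value`, `df`.
#' @export
grouped_expression_test <- function(groups) {
  if (length(groups) < 3)
    stop("need at least 3 groups; use group_mean_compare for two")
  if (any(lengths(groups) == 0)) stop("every group must be nonempty")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Normalized dispersion with batch correction
#'
#' Per batch, each gene's dispersion (variance/mean of the provided values)
#' is z-scored within 20 equal-count bins of the per-gene mean; the combined
#' value is the mean of the per-batch z-scores over the batches where the
#' gene is expressed (mean > 0). Permutation p-values over the assayed gene
#' list come from [empirical_perm_p()].
#'
#' @param m a [tam_counts()] or [tam_norm()].
#' @param batches per-cell batch labels (defaults to the sample ids).
#' @param n_bins number of equal-count mean bins (default 20).
#' @return data.frame (`dispersion_result`): gene, combined normalized
#'   dispersion, rank, perm_p, adj_p, n_batches_expressed; genes expressed
#'   in no batch are excluded with a warning.
#' @export
normalized_dispersion <- function(m, batches = NULL, n_bins = 20L) {
  x <- if (inherits(m, "tam_counts")) m$counts else m$values
  if (is.null(batches)) batches <- m$sample_of_cell
  if (!is.null(names(batches))) batches <- batches[colnames(x)]
  zs <- sapply(unique(batches), function(b) {
    xb <- x[, batches == b, drop = FALSE]
    if (nrow(xb) < 2) stop("need >= 2 genes per batch")
    mu <- rowMeans(xb)
    v <- rowMeans(xb^2) - mu^2
    v <- v * ncol(xb) / max(1, ncol(xb) - 1)
    disp <- ifelse(mu > 0, v / mu, NA_real_)
    z <- rep(NA_real_, length(mu))
    expressed <- mu > 0
    if (any(expressed))
      z[expressed] <- .binned_zscore(mu[expressed], disp[expressed], n_bins)
    z
  })
  zs <- matrix(zs, nrow = nrow(x), dimnames = list(rownames(x), NULL))
  n_expr <- rowSums(!is.na(zs))
  if (any(n_expr == 0)) {
    warning(sum(n_expr == 0), " gene(s) expressed in no batch; excluded")
    zs <- zs[n_expr > 0, , drop = FALSE]
    n_expr <- n_expr[n_expr > 0]
  }
  combined <- rowMeans(zs, na.rm = TRUE)
  res <- empirical_perm_p(combined)
  res$n_batches_expressed <- n_expr[res$gene]
  names(res)[names(res) == "statistic"] <- "norm_dispersion"
  class(res) <- c("dispersion_result", "data.frame")
  res
}

# z-score dispersions within equal-count bins of the mean; bins with < 2
# genes are merged into their lower neighbor (with a warning)
.binned_zscore <- function(mu, disp, n_bins) {
  n <- length(mu)
  n_bins <- max(1L, min(n_bins, floor(n / 2)))
  bin <- ceiling(rank(mu, ties.method = "first") * n_bins / n)
  counts <- table(bin)
  if (any(counts < 2)) {
    warning("mean bin(s) with < 2 genes merged with neighbor")
    for (b in names(counts)[counts < 2]) {
      tgt <- if (as.integer(b) > 1) as.integer(b) - 1L else as.integer(b) + 1L
      bin[bin == as.integer(b)] <- tgt
    }
  }
  z <- numeric(n)
  for (b in unique(bin)) {
    i <- bin == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z
}
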