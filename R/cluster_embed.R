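# Dimensionality reduction (PCA to 5% of genes, UMAP to 2-D), marker-based
# cell typing of the full embedding, and silhouette-selected k-means
# clustering of the macrophage compartment.

#' Embedding and clustering configuration
#'
#' @param pca_fraction fraction of the gene count kept as principal
#'   components (default 0.05, i.e. dimensionality reduced to 5% of genes).
#' @param umap_seed,kmeans_seed integer seeds for the stochastic steps.
#' @param k_range inclusive integer range of k for k-means model selection
#'   (default 2:6).
#' @param n_neighbors UMAP neighborhood size (library default 15).
#' @param coarse_k number of coarse k-means clusters used for marker-based
#'   cell typing of the full embedding.
#' @param silhouette_max_cells silhouette evaluation subsamples to at most
#'   this many cells (the pairwise distance matrix is quadratic in cells);
#'   labels are still fitted on all cells.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(pca_fraction = 0.05,
                             umap_seed = 1L, kmeans_seed = 1L,
                             k_range = 2:6,
                             n_neighbors = 15,
                             coarse_k = 8L,
                             silhouette_max_cells = 4000L) {
  if (pca_fraction <= 0 || pca_fraction > 1)
    stop("pca_fraction must lie in (0, 1]")
  if (min(k_range) < 2) stop("k_range lower bound must be >= 2")
  structure(list(pca_fraction = pca_fraction,
                 umap_seed = as.integer(umap_seed),
                 kmeans_seed = as.integer(kmeans_seed),
                 k_range = as.integer(k_range),
                 n_neighbors = n_neighbors,
                 coarse_k = as.integer(coarse_k),
                 silhouette_max_cells = as.integer(silhouette_max_cells)),
            class = "embedding_config")
}

#' PCA reduction to a fraction of the gene count
#'
#' The number of components is `round(pca_fraction * n_genes)` under
#' round-half-up, clipped to `[1, min(n_cells, n_genes) - 1]`. Deterministic
#' up to component sign.
#'
#' @param m a [tam_norm()].
#' @param cfg an [embedding_config()].
#' @return numeric matrix of component scores, cells x components.
#' @export
pca_reduce <- function(m, cfg = embedding_config()) {
  stopifnot(inherits(m, "tam_norm"))
  x <- t(as.matrix(m$values))               # cells x genes
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 cells and 2 genes")
  if (all(apply(x, 2, var) == 0)) stop("degenerate matrix: all genes constant")
  n_comp <- n_components(ncol(x), cfg$pca_fraction, nrow(x))
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comp)
  scores <- p$x[, seq_len(min(n_comp, ncol(p$x))), drop = FALSE]
  rownames(scores) <- cell_ids(m)
  scores
}

#' Number of principal components retained for a gene count
#'
#' @param n_genes gene count.
#' @param fraction fraction of genes kept (e.g. 0.05).
#' @param n_cells cell count (for the clip upper bound).
#' @return integer component count: round-half-up of `fraction * n_genes`,
#'   clipped to `[1, min(n_cells, n_genes) - 1]`.
#' @export
n_components <- function(n_genes, fraction, n_cells) {
  k <- floor(fraction * n_genes + 0.5)      # round half up
  as.integer(max(1, min(k, min(n_cells, n_genes) - 1)))
}

#' 2-D UMAP embedding of component scores
#'
#' Runs uwot's UMAP with library defaults apart from the seed and the
#' neighborhood size; single-threaded so coordinates are reproducible for a
#' fixed seed.
#'
#' @param scores cells x components matrix from [pca_reduce()].
#' @param cfg an [embedding_config()].
#' @return cells x 2 coordinate matrix (rownames = cell ids).
#' @export
umap_embed <- function(scores, cfg = embedding_config()) {
  if (nrow(scores) < 3) stop("need at least 3 cells to embed")
  if (nrow(scores) <= cfg$n_neighbors)
    stop(sprintf(paste0("only %d cells for n_neighbors = %d; ",
                        "use a smaller neighborhood"),
                 nrow(scores), cfg$n_neighbors))
  set.seed(cfg$umap_seed)
  xy <- uwot::umap(scores, n_neighbors = cfg$n_neighbors, n_components = 2,
                   n_threads = 1, n_sgd_threads = 0)
  dimnames(xy) <- list(rownames(scores), c("UMAP1", "UMAP2"))
  xy
}

#' Marker-based cell typing of the full embedding
#'
#' Over-clusters the 2-D embedding (k-means, `coarse_k` centers) and labels
#' each coarse cluster by the marker family with the highest mean z-scored
#' expression: CD14 for macrophages, CD3D/CD3E/CD3G for T cells, SOX2 for
#' tumor cells. Clusters where no family mean z-score is positive are
#' `unassigned`.
#'
#' @param m a [tam_norm()] containing the marker genes.
#' @param coords 2-D embedding from [umap_embed()].
#' @param cfg an [embedding_config()].
#' @param markers named list of marker families (symbol vectors).
#' @return data.frame: cell_id, sample, cell_type, cluster (coarse), x, y.
#' @export
assign_cell_types <- function(m, coords, cfg = embedding_config(),
                              markers = list(
                                macrophage = "CD14",
                                tcell = c("CD3D", "CD3E", "CD3G"),
                                tumor = "SOX2")) {
  stopifnot(inherits(m, "tam_norm"))
  markers <- lapply(markers, intersect, y = gene_symbols(m))
  if (all(lengths(markers) == 0)) stop("no marker gene present in the matrix")
  markers <- markers[lengths(markers) > 0]

  set.seed(cfg$kmeans_seed)
  k <- min(cfg$coarse_k, nrow(coords) - 1L)
  cl <- kmeans(coords, centers = k, nstart = 10, iter.max = 50)$cluster

  # per-cell family score: mean across the family's genes of the per-gene
  # z-score over all cells
  zmat <- vapply(markers, function(g) {
    v <- as.matrix(m$values[g, , drop = FALSE])
    z <- (v - rowMeans(v)) / apply(v, 1, function(r) max(sd(r), 1e-12))
    colMeans(z)
  }, numeric(ncol(m$values)))

  type_of_cluster <- vapply(sort(unique(cl)), function(ci) {
    mu <- colMeans(zmat[cl == ci, , drop = FALSE])
    if (max(mu) <= 0) "unassigned" else names(markers)[which.max(mu)]
  }, character(1))

  data.frame(cell_id = cell_ids(m),
             sample = unname(m$sample_of_cell),
             cell_type = type_of_cluster[cl],
             cluster = cl,
             x = coords[, 1], y = coords[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean silhouette width of a labeling
#'
#' For more than `max_cells` points a deterministic subsample (fixed by
#' `seed`) is scored; the labels themselves are untouched.
#'
#' @param coords numeric matrix of points.
#' @param labels integer cluster labels.
#' @param max_cells subsample cap for the pairwise-distance computation.
#' @param seed subsample seed.
#' @return mean silhouette width in \[-1, 1\].
#' @export
mean_silhouette <- function(coords, labels, max_cells = 4000L, seed = 1L) {
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  idx <- seq_len(nrow(coords))
  if (nrow(coords) > max_cells) {
    set.seed(seed)
    repeat {
      idx <- sort(sample.int(nrow(coords), max_cells))
      if (length(unique(labels[idx])) >= 2) break
    }
  }
  sil <- cluster::silhouette(labels[idx], dist(coords[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Silhouette-selected k-means clustering of the macrophage embedding
#'
#' Runs k-means on the 2-D embedding for each k in `k_range`, scores each
#' solution by mean silhouette width, and returns the labels of the
#' highest-scoring k.
#'
#' @param coords 2-D macrophage embedding (from the re-embedded macrophage
#'   compartment).
#' @param cfg an [embedding_config()].
#' @return list: `labels` (integer per cell, named), `k` (selected),
#'   `silhouette` (data.frame k, mean_silhouette), `all_labels` (list of
#'   labelings per k).
#' @export
cluster_macrophages <- function(coords, cfg = embedding_config()) {
  k_range <- cfg$k_range
  if (nrow(coords) < max(k_range) + 1)
    stop(sprintf("need more than %d cells for k up to %d",
                 max(k_range), max(k_range)))
  n_distinct <- nrow(unique(coords))
  all_labels <- list()
  sil <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k > n_distinct) next        # k-means undefined beyond distinct points
    set.seed(cfg$kmeans_seed)
    fit <- kmeans(coords, centers = k, nstart = 10, iter.max = 100)
    labels <- setNames(fit$cluster, rownames(coords))
    all_labels[[as.character(k)]] <- labels
    sil[i] <- mean_silhouette(coords, labels,
                              max_cells = cfg$silhouette_max_cells,
                              seed = cfg$kmeans_seed)
  }
  if (all(is.na(sil))) stop("no k in range is feasible for these points")
  best <- k_range[which.max(sil)]
  list(labels = all_labels[[as.character(best)]],
       k = best,
       silhouette = data.frame(k = k_range, mean_silhouette = sil),
       all_labels = all_labels)
}

#' PCA -> UMAP -> typing on a normalized matrix
#'
#' Convenience wrapper running the full embedding stage; used both for the
#' global cohort and the re-embedded macrophage compartment.
#'
#' @param m a [tam_norm()].
#' @param cfg an [embedding_config()].
#' @return list: `scores` (PCA), `coords` (UMAP), `annotation`
#'   (cell typing; NULL if `type_cells = FALSE`).
#' @param type_cells run marker-based typing on the embedding.
#' @export
embed_cohort <- function(m, cfg = embedding_config(), type_cells = TRUE) {
  scores <- pca_reduce(m, cfg)
  coords <- umap_embed(scores, cfg)
  ann <- if (type_cells) assign_cell_types(m, coords, cfg) else NULL
  list(scores = scores, coords = coords, annotation = ann)
}
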