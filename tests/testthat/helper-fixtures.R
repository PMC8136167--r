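# Shared fixtures, built once per test run.

# a dense genes x cells matrix -> tam_norm with values taken as-is
as_norm <- function(mat, samples = NULL) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%02d", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- rep("s1", ncol(mat))
  tam_norm(mat, stats::setNames(samples, colnames(mat)))
}

as_counts <- function(mat, samples = NULL) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%02d", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- rep("s1", ncol(mat))
  tam_counts(mat, stats::setNames(samples, colnames(mat)))
}

# small default-structure cohort reused by several files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_samples = 8,
                                              cells_per_sample = 150,
                                              seed = 3))
    cache
  }
})

# preprocessed + embedded small cohort (one UMAP run shared across files)
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- small_cohort()
      pp <- preprocess_cohort(co$counts, co$truth$panel)
      ecfg <- embedding_config(umap_seed = 11, kmeans_seed = 12)
      emb <- embed_cohort(pp$normalized, ecfg)
      mac <- emb$annotation$cell_id[emb$annotation$cell_type == "macrophage"]
      mac_norm <- subset_cells(pp$normalized, cells = mac)
      mac_emb <- embed_cohort(mac_norm, ecfg, type_cells = FALSE)
      cl <- cluster_macrophages(mac_emb$coords, ecfg)
      cache <<- list(cohort = co, norm = pp$normalized, emb = emb,
                     mac_norm = mac_norm, mac_coords = mac_emb$coords,
                     clusters = cl, ecfg = ecfg)
    }
    cache
  }
})

# which cluster label is the planted scavenger cluster (majority vote)
scavenger_label <- function(run) {
  truth <- run$cohort$truth$cells
  sub <- truth$subpop[match(names(run$clusters$labels), truth$cell_id)]
  tab <- table(run$clusters$labels, sub)
  rownames(tab)[which.max(tab[, "scavenger"])]
}

write_toy_gmt <- function(path, sets) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}
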