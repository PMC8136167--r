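# End-to-end orchestration: a declarative run configuration, staged
# execution (preprocess -> embed/type -> macrophage clustering -> markers ->
# signatures -> GSEA; survival independently), structured per-stage logging
# and a provenance manifest.

#' Declarative pipeline run configuration
#'
#' All analysis thresholds default to the pipeline's standard values: FDR
#' 0.05, PCA fraction 0.05, silhouette k range 2..6, GSEA weight 1 with
#' 1000 phenotype permutations. Every stochastic stage has an explicit
#' seed; validation fails if one is missing.
#'
#' @param simulate a [cohort_config()] to generate inputs, or NULL to read
#'   them from `input_dir`.
#' @param input_dir directory with matrix.mtx/genes.tsv/barcodes.tsv (and
#'   optionally panel.txt), used when `simulate` is NULL.
#' @param panel_path optional path to a one-symbol-per-line panel file.
#' @param gmt_path optional GMT file for the GSEA stage (NULL skips GSEA).
#' @param query_gene marker gene anchoring the scavenger-side analyses.
#' @param stages character vector of stage names to run, in order.
#' @param fdr_threshold adjusted-p significance threshold.
#' @param pca_fraction,k_range,n_neighbors embedding parameters
#'   (see [embedding_config()]).
#' @param gsea_weight,gsea_permutations GSEA parameters.
#' @param umap_seed,kmeans_seed,gsea_seed stage seeds (required).
#' @param outdir output directory, or NULL to skip writing files.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulate = cohort_config(),
                       input_dir = NULL,
                       panel_path = NULL,
                       gmt_path = NULL,
                       query_gene = "MARCO",
                       stages = c("preprocess", "cluster", "markers",
                                  "scores", "gsea"),
                       fdr_threshold = 0.05,
                       pca_fraction = 0.05,
                       k_range = 2:6,
                       n_neighbors = 15,
                       gsea_weight = 1,
                       gsea_permutations = 1000,
                       umap_seed = 1L, kmeans_seed = 1L, gsea_seed = 1L,
                       outdir = NULL) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param cfg a `run_config`.
#' @return the config, invisibly; errors on any violation.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$input_dir))
    stop("validation: either simulate or input_dir must be given")
  for (s in c("umap_seed", "kmeans_seed", "gsea_seed"))
    if (is.null(cfg[[s]]) || length(cfg[[s]]) != 1 || is.na(cfg[[s]]))
      stop("validation: missing seed: ", s)
  for (p in c("input_dir", "panel_path", "gmt_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("validation: path does not exist: ", cfg[[p]])
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1)
    stop("validation: fdr_threshold must lie in (0, 1]")
  invisible(cfg)
}

#' Round-trip a run configuration through YAML
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return for `write_run_config`, `path` invisibly; for `read_run_config`,
#'   the parsed `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  lst <- unclass(cfg)
  if (!is.null(lst$simulate)) {
    sim <- unclass(lst$simulate)
    # named atomic vectors must become maps, or YAML drops the names
    sim$cell_type_fractions <- as.list(sim$cell_type_fractions)
    sim$subpop_fractions_by_idh1 <- as.list(sim$subpop_fractions_by_idh1)
    lst$simulate <- sim
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$simulate)) {
    sim <- lst$simulate
    sim$cell_type_fractions <- unlist(sim$cell_type_fractions)
    sim$subpop_fractions_by_idh1 <- unlist(sim$subpop_fractions_by_idh1)
    lst$simulate <- do.call(cohort_config, sim)
  }
  lst$k_range <- as.integer(lst$k_range)
  cfg <- structure(lst, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Run the single-cell analysis pipeline
#'
#' Executes the configured stages in order: preprocess (filter, merge,
#' normalize, panel-restrict), cluster (global embedding + cell typing,
#' macrophage re-embedding + silhouette-selected k-means), markers
#' (enrichment + permutation p per macrophage cluster, scavenger cluster
#' identified by the query gene), scores (paired macrophage-tumor
#' cross-talk correlation on the recruitment panel), gsea (if a GMT is
#' configured). Each stage is logged with wall time and shapes; outputs and
#' a provenance manifest are written when `outdir` is set. Re-running the
#' same config reproduces identical result files.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return a `run_report` list: `annotation`, `macro_clusters`,
#'   `marker_tables`, `scavenger_cluster`, `crosstalk`, `gsea`,
#'   `provenance`, `log`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_run_config(cfg)
  log <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log[[name]] <<- sprintf("%s: %.1fs", name, dt)
    if (!quiet) message(log[[name]])
    out
  }
  report <- list()
  ecfg <- embedding_config(pca_fraction = cfg$pca_fraction,
                           umap_seed = cfg$umap_seed,
                           kmeans_seed = cfg$kmeans_seed,
                           k_range = cfg$k_range,
                           n_neighbors = cfg$n_neighbors)

  # inputs
  if (!is.null(cfg$simulate)) {
    cohort <- t_stage("simulate", generate_cohort(cfg$simulate))
    raw <- cohort$counts
    panel <- cohort$truth$panel
    report$truth <- cohort$truth
  } else {
    raw <- t_stage("read", read_cohort_mtx(cfg$input_dir))
    panel <- NULL
  }
  if (!is.null(cfg$panel_path)) panel <- read_gene_panel(cfg$panel_path)

  if ("preprocess" %in% cfg$stages) {
    pp <- t_stage("preprocess", preprocess_cohort(raw, panel))
    norm <- pp$normalized
    report$preprocess_provenance <- pp$provenance
  } else stop("the preprocess stage cannot be skipped")

  if ("cluster" %in% cfg$stages) {
    emb <- t_stage("embed", embed_cohort(norm, ecfg))
    report$annotation <- emb$annotation
    mac_ids <- emb$annotation$cell_id[emb$annotation$cell_type ==
                                        "macrophage"]
    if (length(mac_ids) <= max(cfg$k_range))
      stop("stage 'cluster' failed: too few macrophages identified")
    mac_norm <- subset_cells(norm, cells = mac_ids)
    mac_emb <- t_stage("macro_embed",
                       embed_cohort(mac_norm, ecfg, type_cells = FALSE))
    report$macro_clusters <- t_stage("macro_cluster",
                                     cluster_macrophages(mac_emb$coords,
                                                         ecfg))
    report$macro_coords <- mac_emb$coords
    report$macro_norm <- mac_norm
  }

  if ("markers" %in% cfg$stages) {
    if (is.null(report$macro_clusters))
      stop("stage 'markers' failed: cluster stage did not run")
    labels <- report$macro_clusters$labels
    clusters <- sort(unique(labels))
    report$marker_tables <- t_stage("markers", lapply(
      setNames(clusters, paste0("cluster", clusters)),
      function(ci) marker_table(report$macro_norm, labels, ci)))
    if (cfg$query_gene %in% gene_symbols(report$macro_norm)) {
      qstat <- vapply(clusters, function(ci)
        enrichment_statistic(report$macro_norm, labels, ci)[cfg$query_gene],
        numeric(1))
      report$scavenger_cluster <- clusters[which.max(qstat)]
    }
  }

  if ("scores" %in% cfg$stages && !is.null(report$annotation)) {
    report$crosstalk <- t_stage("scores", tryCatch(
      paired_crosstalk_correlation(norm, report$annotation,
                                   query_gene = cfg$query_gene),
      error = function(e) {
        warning("cross-talk correlation skipped: ", conditionMessage(e))
        NULL
      }))
  }

  if ("gsea" %in% cfg$stages && !is.null(cfg$gmt_path) &&
      !is.null(report$macro_norm)) {
    sets <- read_gmt(cfg$gmt_path)
    pheno <- as.numeric(report$macro_norm$values[cfg$query_gene, ])
    report$gsea <- t_stage("gsea", phenotype_permutation(
      report$macro_norm, pheno, sets,
      gsea_config(cfg$gsea_weight, cfg$gsea_permutations, cfg$gsea_seed)))
  }

  report$log <- unlist(log)
  report$provenance <- list(
    package_version = as.character(packageVersion("gliotam")),
    seeds = list(umap = cfg$umap_seed, kmeans = cfg$kmeans_seed,
                 gsea = cfg$gsea_seed,
                 simulate = if (!is.null(cfg$simulate)) cfg$simulate$seed),
    parameters = list(pca_fraction = cfg$pca_fraction,
                      k_range = cfg$k_range,
                      fdr_threshold = cfg$fdr_threshold,
                      gsea_weight = cfg$gsea_weight,
                      gsea_permutations = cfg$gsea_permutations),
    shapes = list(genes = nrow(norm$values), cells = ncol(norm$values)))

  if (!is.null(cfg$outdir)) write_run_outputs(report, cfg$outdir)
  class(report) <- "run_report"
  report
}

# write result tables + provenance manifest with per-file checksums
write_run_outputs <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(obj, name, writer) {
    path <- file.path(outdir, name)
    writer(obj, path)
    written <<- c(written, path)
  }
  if (!is.null(report$annotation))
    put(report$annotation, "annotation.csv",
        function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(report$macro_clusters))
    put(report$macro_clusters$silhouette, "silhouette.csv",
        function(o, p) write.csv(o, p, row.names = FALSE))
  for (nm in names(report$marker_tables))
    put(report$marker_tables[[nm]], paste0("markers_", nm, ".tsv"),
        function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE))
  if (!is.null(report$crosstalk))
    put(report$crosstalk$per_sample, "crosstalk_per_sample.csv",
        function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(report$gsea))
    put(report$gsea, "gsea_report.tsv",
        function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE))
  prov <- report$provenance
  prov$files <- as.list(tools::md5sum(written))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("gliotam run report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  if (!is.null(x$macro_clusters))
    cat(sprintf("  selected k = %d (mean silhouette %.3f)\n",
                x$macro_clusters$k,
                max(x$macro_clusters$silhouette$mean_silhouette)))
  if (!is.null(x$scavenger_cluster))
    cat(sprintf("  scavenger cluster: %s\n", x$scavenger_cluster))
  if (!is.null(x$crosstalk))
    cat(sprintf("  cross-talk Spearman rho = %.3f (p = %.4g, n = %d)\n",
                x$crosstalk$rho, x$crosstalk$p_value, x$crosstalk$n))
  invisible(x)
}
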