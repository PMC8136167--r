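# Synthetic multi-sample glioma cohorts with planted structure:
# three cell types (tumor / T cell / macrophage), two opposed macrophage
# programs (scavenger vs inflammatory), sample-level IDH1 status gating the
# scavenger fraction, and tumor-cell recruitment factors coupled to it.

.SCAV_PROGRAM <- c("MARCO", "CD163", "MSR1", "MRC1", "CHIT1",
                   "GPNMB", "LGALS3", "FABP5", "CSTB", "ANXA2")
.INFL_PROGRAM <- c("CCL4", "IL1B", "TMEM119", "CCL3", "TNF",
                   "CXCL8", "IL1A", "P2RY12", "CX3CR1", "NFKBIA")
.TYPE_MARKERS <- list(macrophage = "CD14",
                      tcell = c("CD3D", "CD3E"),
                      tumor = "SOX2")
.RECRUITMENT <- c("CSF1", "CSF2", "HGF", "CCL2", "MIF", "CXCL12",
                  "TGFB1", "TGFB2", "TGFB3", "IL10", "SPP1", "MFGE8")

#' Configuration for the synthetic single-cell cohort generator
#'
#' Defines the generative model: cells are assigned a type by sample-level
#' multinomial draws, macrophages are split between a scavenger (MARCO-like)
#' and an inflammatory (CCL4/IL1B-like) program with a sample-specific
#' scavenger fraction whose mean depends on the sample's IDH1 status, and UMI
#' counts are negative binomial around gene/type/program means scaled by a
#' log-normal per-cell library factor. Tumor cells additionally express a
#' 12-symbol recruitment-factor program whose sample-level log-fold tracks
#' the sample's true scavenger fraction, blurred by noise scaled by
#' `1 - crosstalk_coupling`.
#'
#' @param n_samples number of samples (patients).
#' @param cells_per_sample cells profiled per sample.
#' @param n_genes total genes in the matrix (planted genes plus fillers).
#' @param cell_type_fractions named simplex weights over
#'   `c(tumor, tcell, macrophage)`; must sum to 1.
#' @param subpop_fractions_by_idh1 named vector `c(WT=, mut=)`: the mean
#'   fraction of a sample's macrophages carrying the scavenger program, by
#'   the sample's IDH1 status. A value of exactly 0 plants no scavenger
#'   macrophages in samples of that status.
#' @param marker_log_fold positive log2 fold elevation of planted marker
#'   genes in their home population. The defining marker of each macrophage
#'   program is elevated further (MARCO and CCL4 by one extra log2 unit,
#'   IL1B by half a unit), so each program has an unambiguous top gene.
#' @param crosstalk_coupling in \[0, 1\]; 1 makes the tumor recruitment-factor
#'   level a deterministic function of the sample's scavenger fraction, 0
#'   leaves it dominated by sample-level noise.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param library_size_mean expected UMIs per cell at baseline.
#' @param idh1_mut_fraction fraction of samples that are IDH1-mutated.
#' @param scav_concentration Beta concentration of the per-sample scavenger
#'   fraction around its status-level mean.
#' @param seed integer random seed; fixes every draw.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_samples = 20,
                          cells_per_sample = 500,
                          n_genes = 300,
                          cell_type_fractions = c(tumor = 0.5, tcell = 0.2,
                                                  macrophage = 0.3),
                          subpop_fractions_by_idh1 = c(WT = 0.3, mut = 0.0),
                          marker_log_fold = 3,
                          crosstalk_coupling = 0.7,
                          nb_dispersion = 2,
                          library_size_mean = 2000,
                          idh1_mut_fraction = 0.2,
                          scav_concentration = 30,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              cells_per_sample = as.integer(cells_per_sample),
              n_genes = as.integer(n_genes),
              cell_type_fractions = cell_type_fractions,
              subpop_fractions_by_idh1 = subpop_fractions_by_idh1,
              marker_log_fold = marker_log_fold,
              crosstalk_coupling = crosstalk_coupling,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              idh1_mut_fraction = idh1_mut_fraction,
              scav_concentration = scav_concentration,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  f <- cfg$cell_type_fractions
  if (!setequal(names(f), c("tumor", "tcell", "macrophage")))
    stop("cell_type_fractions must be named tumor/tcell/macrophage")
  if (abs(sum(f) - 1) > 1e-12) stop("cell_type_fractions must sum to 1")
  sp <- cfg$subpop_fractions_by_idh1
  if (!setequal(names(sp), c("WT", "mut")))
    stop("subpop_fractions_by_idh1 must be named WT/mut")
  if (any(sp < 0 | sp > 1)) stop("subpop fractions must lie in [0, 1]")
  if (cfg$crosstalk_coupling < 0 || cfg$crosstalk_coupling > 1)
    stop("crosstalk_coupling must lie in [0, 1]")
  if (cfg$marker_log_fold <= 0) stop("marker_log_fold must be positive")
  if (cfg$n_samples < 1 || cfg$cells_per_sample < 1)
    stop("n_samples and cells_per_sample must be positive")
  n_planted <- length(planted_genes())
  if (cfg$n_genes < n_planted)
    stop(sprintf("n_genes must be at least %d (the planted marker genes)",
                 n_planted))
  if (f[["macrophage"]] == 0 && any(sp > 0))
    stop("zero macrophage fraction but nonzero subpopulation fractions")
  invisible(cfg)
}

planted_genes <- function() {
  unique(c(unlist(.TYPE_MARKERS, use.names = FALSE),
           .SCAV_PROGRAM, .INFL_PROGRAM, .RECRUITMENT))
}

#' Generate a synthetic multi-sample single-cell cohort
#'
#' Draws a cohort under the model described in [cohort_config()]. Output is
#' bit-reproducible for a fixed config (including seed).
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list with elements
#'   \describe{
#'     \item{counts}{a [tam_counts()] (genes x cells)}
#'     \item{truth}{list: `cells` (cell_id, sample, cell_type, subpop),
#'       `samples` (sample, idh1, scav_fraction), `markers` (planted program
#'       and marker symbol lists), `panel` (an immune-style gene panel with
#'       known overlap), `panel_overlap` (expected intersection size with the
#'       matrix)}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)

  planted <- planted_genes()
  n_fill <- config$n_genes - length(planted)
  fillers <- sprintf("FILL%03d", seq_len(n_fill))
  genes <- c(planted, fillers)

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  n_mut <- round(config$n_samples * config$idh1_mut_fraction)
  idh1 <- rep(c("WT", "mut"),
              c(config$n_samples - n_mut, n_mut))

  sp <- config$subpop_fractions_by_idh1
  conc <- config$scav_concentration
  scav_frac <- vapply(idh1, function(st) {
    f <- sp[[st]]
    if (f == 0 || f == 1) f else rbeta(1, f * conc, (1 - f) * conc)
  }, numeric(1))

  # per-cell type and subpopulation assignment
  types <- c("tumor", "tcell", "macrophage")
  cell_sample <- character(0); cell_type <- character(0)
  cell_subpop <- character(0)
  for (i in seq_along(samples)) {
    n_by_type <- as.vector(stats::rmultinom(
      1, config$cells_per_sample, config$cell_type_fractions[types]))
    ty <- rep(types, n_by_type)
    sub <- rep("none", length(ty))
    is_mac <- ty == "macrophage"
    if (any(is_mac)) {
      scav <- rbinom(sum(is_mac), 1, scav_frac[i]) == 1
      sub[is_mac] <- ifelse(scav, "scavenger", "inflammatory")
    }
    cell_sample <- c(cell_sample, rep(samples[i], length(ty)))
    cell_type <- c(cell_type, ty)
    cell_subpop <- c(cell_subpop, sub)
  }
  n_cells <- length(cell_type)
  cell_id <- sprintf("%s_c%04d", cell_sample,
                     stats::ave(seq_len(n_cells), cell_sample,
                                FUN = seq_along))

  # baseline relative expression; planted genes pinned at the median filler
  # level so the configured fold is the literal home-vs-away mean ratio
  rel <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  rel[seq_along(planted)] <- median(rel)
  base <- rel / sum(rel) * config$library_size_mean
  names(base) <- genes

  # log2 fold by cell group
  fold <- matrix(0, nrow = config$n_genes, ncol = n_cells,
                 dimnames = list(genes, NULL))
  mlf <- config$marker_log_fold
  is_mac <- cell_type == "macrophage"
  fold["CD14", is_mac] <- mlf
  fold[c("CD3D", "CD3E"), cell_type == "tcell"] <- mlf
  fold["SOX2", cell_type == "tumor"] <- mlf
  fold[.SCAV_PROGRAM, cell_subpop == "scavenger"] <- mlf
  fold[.INFL_PROGRAM, cell_subpop == "inflammatory"] <- mlf
  # each program has a dominant defining marker (and a runner-up on the
  # inflammatory side), elevated above the rest of its program
  fold["MARCO", cell_subpop == "scavenger"] <- mlf + 1
  fold["CCL4", cell_subpop == "inflammatory"] <- mlf + 1
  fold["IL1B", cell_subpop == "inflammatory"] <- mlf + 0.5

  # recruitment factors in tumor cells: sample-level log2 fold tracks the
  # true scavenger fraction; noise shrinks as coupling -> 1
  noise <- rnorm(length(samples), 0, 1) * (1 - config$crosstalk_coupling)
  recruit_lfc <- pmax(0, mlf * scav_frac + noise)
  names(recruit_lfc) <- samples
  is_tumor <- cell_type == "tumor"
  fold[.RECRUITMENT, is_tumor] <-
    rep(recruit_lfc[cell_sample[is_tumor]], each = length(.RECRUITMENT))

  lib <- rlnorm(n_cells, meanlog = -0.5^2 / 2, sdlog = 0.5)

  mu <- base * 2^fold * rep(lib, each = config$n_genes)
  counts <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                   nrow = config$n_genes,
                   dimnames = list(genes, cell_id))

  # guard against all-zero cells at tiny library sizes (would break TPK)
  empty <- colSums(counts) == 0
  if (any(empty)) counts[1L, empty] <- 1L

  panel <- c(planted, fillers[seq_len(min(n_fill, floor(n_fill / 2)))],
             sprintf("DECOY%02d", 1:20))

  cohort <- list(
    counts = tam_counts(counts, setNames(cell_sample, cell_id)),
    truth = list(
      cells = data.frame(cell_id = cell_id, sample = cell_sample,
                         cell_type = cell_type, subpop = cell_subpop,
                         stringsAsFactors = FALSE),
      samples = data.frame(sample = samples, idh1 = idh1,
                           scav_fraction = unname(scav_frac),
                           recruit_lfc = unname(recruit_lfc),
                           stringsAsFactors = FALSE),
      markers = list(scavenger = .SCAV_PROGRAM,
                     inflammatory = .INFL_PROGRAM,
                     type_markers = .TYPE_MARKERS,
                     recruitment = .RECRUITMENT),
      panel = gene_panel("synthetic_immune_panel", panel),
      panel_overlap = length(intersect(panel, genes))))
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d cells, %d samples (%d IDH1-mut)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              nrow(x$truth$samples), sum(x$truth$samples$idh1 == "mut")))
  invisible(x)
}

#' Configuration for the synthetic bulk survival cohort
#'
#' Event times are exponential with per-patient hazard
#' `baseline_hazard * exp(true_log_hr * z + age/MGMT effects)` where `z` is
#' the standard-normal expression covariate of the query gene; censoring is
#' independent exponential.
#'
#' @param n_patients cohort size.
#' @param true_log_hr per-unit-z log hazard ratio of the expression covariate.
#' @param baseline_hazard exponential baseline rate per unit time (> 0).
#' @param censor_rate rate of the independent censoring distribution (>= 0;
#'   0 disables censoring).
#' @param age_effect,mgmt_effect optional log-hazard effects of the age
#'   (per decade above 60) and MGMT-methylation covariates.
#' @param seed integer random seed.
#' @return a `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_patients = 500,
                                true_log_hr = log(1.19),
                                baseline_hazard = 0.1,
                                censor_rate = 0.025,
                                age_effect = 0,
                                mgmt_effect = 0,
                                seed = 1L) {
  if (n_patients <= 0) stop("n_patients must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 true_log_hr = true_log_hr,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 age_effect = age_effect, mgmt_effect = mgmt_effect,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Generate a matched bulk expression + survival cohort
#'
#' @param config a [survival_sim_config()].
#' @param gene symbol of the query gene carrying the planted hazard effect.
#' @param n_noise_genes extra uninformative genes in the expression table.
#' @return list with `expression` (genes x patients numeric matrix, linear
#'   scale) and `clinical` (data.frame: sample, time, event, age, mgmt, idh1,
#'   expression_z — the true covariate).
#' @export
generate_bulk_survival <- function(config, gene = "MARCO",
                                   n_noise_genes = 20) {
  stopifnot(inherits(config, "survival_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  z <- rnorm(n)
  age <- rnorm(n, 60, 10)
  mgmt <- rbinom(n, 1, 0.4)
  lp <- config$true_log_hr * z +
    config$age_effect * (age - 60) / 10 +
    config$mgmt_effect * mgmt
  t_event <- rexp(n, rate = config$baseline_hazard * exp(lp))
  t_cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  ids <- sprintf("P%04d", seq_len(n))

  # query gene on linear scale: log2 expression is 8 + z, so per-cohort
  # log + z-scoring recovers z exactly (up to the sample mean/sd)
  expr <- matrix(2^rnorm(n_noise_genes * n, 6, 1), nrow = n_noise_genes,
                 dimnames = list(sprintf("NOISE%02d", seq_len(n_noise_genes)),
                                 ids))
  expr <- rbind(matrix(2^(8 + z), nrow = 1, dimnames = list(gene, ids)),
                expr)

  clinical <- data.frame(sample = ids, time = time, event = event,
                         age = age, mgmt = mgmt, idh1 = "WT",
                         expression_z = z, stringsAsFactors = FALSE)
  list(expression = expr, clinical = clinical)
}

#' Write a synthetic cohort to disk
#'
#' Writes the count matrix as 1-based coordinate Matrix Market
#' (`matrix.mtx`, genes x cells) with `genes.tsv` / `barcodes.tsv` sidecars
#' (barcodes carry the sample id in a second column), plus
#' `truth_cells.csv` and `truth_samples.csv`, and the planted panel as
#' `panel.txt` (one symbol per line).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$counts
  writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  write.table(data.frame(barcode = colnames(m$counts),
                         sample = unname(m$sample_of_cell)),
              file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.csv(cohort$truth$cells, file.path(dir, "truth_cells.csv"),
            row.names = FALSE)
  write.csv(cohort$truth$samples, file.path(dir, "truth_samples.csv"),
            row.names = FALSE)
  writeLines(cohort$truth$panel$symbols, file.path(dir, "panel.txt"))
  invisible(dir)
}

#' Write a synthetic bulk survival cohort to disk
#'
#' Writes `expression.tsv` (genes x samples) and `clinical.csv`
#' (sample, time, event, age, mgmt, idh1).
#'
#' @param bulk result of [generate_bulk_survival()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bulk_survival <- function(bulk, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(bulk$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.csv(bulk$clinical[, c("sample", "time", "event", "age", "mgmt",
                              "idh1")],
            file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}
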