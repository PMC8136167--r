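test_that("config validation rejects inconsistent cohorts", {
  expect_error(cohort_config(cell_type_fractions =
                               c(tumor = 0.6, tcell = 0.3, macrophage = 0.2)),
               "sum to 1")
  expect_error(cohort_config(n_genes = 10), "planted")
  expect_error(cohort_config(cell_type_fractions =
                               c(tumor = 0.7, tcell = 0.3, macrophage = 0),
                             subpop_fractions_by_idh1 = c(WT = 0.3, mut = 0)),
               "zero macrophage fraction")
  expect_error(cohort_config(subpop_fractions_by_idh1 = c(WT = 1.2, mut = 0)),
               "\\[0, 1\\]")
})

test_that("generation is bit-reproducible and labels cover every cell once", {
  cfg <- cohort_config(n_samples = 3, cells_per_sample = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  # truth covers each cell exactly once, in matrix order
  expect_identical(a$truth$cells$cell_id, cell_ids(a$counts))
  expect_false(anyDuplicated(a$truth$cells$cell_id) > 0)
  # planted markers all exist in the matrix
  expect_true(all(unlist(a$truth$markers[c("scavenger", "inflammatory",
                                           "recruitment")]) %in%
                    gene_symbols(a$counts)))
  # counts are nonnegative integers
  expect_true(all(a$counts$counts@x >= 0))
  expect_identical(a$counts$counts@x, round(a$counts$counts@x))
})

test_that("zero mutant subpopulation fraction plants no scavenger macrophages", {
  co <- small_cohort()
  truth <- co$truth
  mut_samples <- truth$samples$sample[truth$samples$idh1 == "mut"]
  mut_cells <- truth$cells[truth$cells$sample %in% mut_samples, ]
  expect_gt(nrow(mut_cells), 0)
  expect_false(any(mut_cells$subpop == "scavenger"))
  expect_true(all(truth$samples$scav_fraction[truth$samples$idh1 == "mut"] == 0))
})

test_that("planted marker fold is recovered in mean counts (Monte Carlo)", {
  cfg <- cohort_config(n_samples = 4, cells_per_sample = 600,
                       cell_type_fractions = c(tumor = 0.1, tcell = 0.1,
                                               macrophage = 0.8),
                       subpop_fractions_by_idh1 = c(WT = 0.5, mut = 0.5),
                       marker_log_fold = 3, idh1_mut_fraction = 0,
                       seed = 7)
  co <- generate_cohort(cfg)
  truth <- co$truth$cells
  counts <- co$counts$counts
  scav <- truth$cell_id[truth$subpop == "scavenger"]
  infl <- truth$cell_id[truth$subpop == "inflammatory"]
  expect_gt(length(scav), 200)
  # ordinary program gene: home-vs-away mean ratio is the configured fold
  ratio <- mean(counts["CD163", scav]) / mean(counts["CD163", infl])
  expect_gt(ratio, 2^3 * 0.8)
  expect_lt(ratio, 2^3 * 1.25)
  # the program-defining marker carries one extra log2 unit
  ratio_top <- mean(counts["MARCO", scav]) / mean(counts["MARCO", infl])
  expect_gt(ratio_top, 2^4 * 0.8)
  expect_lt(ratio_top, 2^4 * 1.25)
})

test_that("marginal gene means converge to the generative means", {
  # single population, no subpop structure: mean count per gene must match
  # base * 2^fold within 1% at >= 1e4 cells (informative genes averaged)
  cfg <- cohort_config(n_samples = 2, cells_per_sample = 6000,
                       cell_type_fractions = c(tumor = 0, tcell = 0,
                                               macrophage = 1),
                       subpop_fractions_by_idh1 = c(WT = 1, mut = 1),
                       idh1_mut_fraction = 0, seed = 9)
  co <- generate_cohort(cfg)
  # every cell is a scavenger macrophage: MARCO mean = base_MARCO * 2^mlf.
  # base is internal, so check the ratio to a filler gene of equal base:
  # planted genes share the median filler base by construction.
  counts <- co$counts$counts
  m_cd163 <- mean(counts["CD163", ])
  m_cd14 <- mean(counts["CD14", ])  # same base, same fold in macrophages
  expect_equal(m_cd163 / m_cd14, 1, tolerance = 0.02)
  m_sox2 <- mean(counts["SOX2", ])  # same base, fold 1 here (no tumor cells)
  expect_equal(m_cd163 / m_sox2, 2^3, tolerance = 0.03)
})

test_that("crosstalk correlation strengthens with coupling", {
  cors <- vapply(c(0, 0.9), function(cc) {
    rhos <- vapply(1:5, function(s) {
      co <- generate_cohort(cohort_config(n_samples = 12,
                                          cells_per_sample = 80,
                                          crosstalk_coupling = cc,
                                          subpop_fractions_by_idh1 =
                                            c(WT = 0.4, mut = 0.05),
                                          seed = 100 + s))
      st <- co$truth$samples
      tumor_cells <- co$truth$cells[co$truth$cells$cell_type == "tumor", ]
      rec <- colMeans(
        as.matrix(co$counts$counts[co$truth$markers$recruitment,
                                   tumor_cells$cell_id]))
      rec_by_sample <- tapply(rec, tumor_cells$sample, mean)
      cor(st$scav_fraction, as.numeric(rec_by_sample[st$sample]),
          method = "spearman")
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_gt(cors[2], cors[1])
  expect_gt(cors[2], 0.5)
})

test_that("survival generator honors censoring and the null", {
  cfg0 <- survival_sim_config(n_patients = 200, censor_rate = 0, seed = 5)
  bulk <- generate_bulk_survival(cfg0)
  expect_true(all(bulk$clinical$event))
  expect_equal(nrow(bulk$clinical), 200)
  expect_identical(colnames(bulk$expression), bulk$clinical$sample)

  cfg_c <- survival_sim_config(n_patients = 400, censor_rate = 0.1,
                               baseline_hazard = 0.1, seed = 6)
  bulk_c <- generate_bulk_survival(cfg_c)
  expect_lt(mean(bulk_c$clinical$event), 1)
  expect_true(all(bulk_c$clinical$time >= 0))

  expect_error(survival_sim_config(n_patients = 0), "positive")
  expect_error(survival_sim_config(baseline_hazard = 0), "> 0")
})

test_that("null hazard yields calibrated log-rank p-values", {
  ps <- vapply(1:20, function(s) {
    bulk <- generate_bulk_survival(
      survival_sim_config(n_patients = 120, true_log_hr = 0,
                          censor_rate = 0.02, seed = 1000 + s))
    clin <- bulk$clinical
    g <- dichotomize_median(stats::setNames(clin$expression_z, clin$sample))
    km_logrank(clin, g)$p_value
  }, numeric(1))
  # under the null, p is uniform across seeds
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort and survival writers produce readable sidecar files", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_samples = 2, cells_per_sample = 40,
                                      seed = 2))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("matrix.mtx", "genes.tsv",
                                               "barcodes.tsv",
                                               "truth_cells.csv",
                                               "panel.txt")))))
  back <- read_cohort_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(co$counts$counts))
  expect_identical(unname(back$sample_of_cell),
                   unname(co$counts$sample_of_cell))

  bulk <- generate_bulk_survival(survival_sim_config(n_patients = 30, seed = 1))
  write_bulk_survival(bulk, dir)
  clin <- read_clinical(file.path(dir, "clinical.csv"))
  expect_identical(clin$sample, bulk$clinical$sample)
  expect_type(clin$event, "logical")
})
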