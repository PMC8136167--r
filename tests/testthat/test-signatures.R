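test_that("signature scores are centered means of centered expression", {
  # identical cells -> all scores 0
  m <- as_norm(matrix(2, 3, 5, dimnames = list(c("A", "B", "C"), NULL)))
  expect_true(all(signature_score(m, set = c("A", "B")) == 0))

  # half the cells overexpress the set uniformly by delta -> scores +/- delta/2
  delta <- 1.4
  vals <- matrix(1, 2, 6, dimnames = list(c("A", "B"), NULL))
  vals[, 1:3] <- 1 + delta
  sc <- signature_score(as_norm(vals), set = c("A", "B"))
  expect_equal(unname(sc), rep(c(delta / 2, -delta / 2), each = 3))

  # scores have numerically zero mean over the scored population
  set.seed(12)
  big <- as_norm(matrix(abs(rnorm(40 * 30)), 40, 30))
  sc2 <- signature_score(big, set = rownames(big$values)[1:7])
  expect_lt(abs(mean(sc2)), 1e-10)
})

test_that("signature score invariances hold", {
  set.seed(13)
  vals <- matrix(abs(rnorm(10 * 20)), 10, 20,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  set <- c("g01", "g03", "g07")
  base <- signature_score(as_norm(vals), set = set)
  # adding a per-gene constant is absorbed by centering
  shifted <- vals + matrix(seq_len(10), 10, 20)
  expect_equal(signature_score(as_norm(shifted), set = set), base)
  # scaling all genes by c > 0 scales scores by c
  expect_equal(signature_score(as_norm(vals * 3), set = set), base * 3)
  # absent genes are dropped; all-absent errors
  with_absent <- signature_score(as_norm(vals), set = c(set, "NOPE"))
  expect_equal(with_absent, base)
  expect_error(signature_score(as_norm(vals), set = "NOPE"), "no set gene")
})

test_that("planted program concentrates in its home subpopulation", {
  run <- small_run()
  truth <- run$cohort$truth
  scav_set <- setdiff(truth$markers$scavenger, "MARCO")
  sc <- signature_score(run$mac_norm, set = scav_set)
  sub <- truth$cells$subpop[match(names(sc), truth$cells$cell_id)]
  expect_gt(mean(sc[sub == "scavenger"]), mean(sc[sub == "inflammatory"]))
})

test_that("compartment comparison detects a macrophage-exclusive program", {
  run <- small_run()
  truth <- run$cohort$truth
  ann <- data.frame(cell_id = truth$cells$cell_id,
                    sample = truth$cells$sample,
                    cell_type = truth$cells$cell_type)
  # a program carried by (essentially) all macrophages and no tumor cells:
  # the pan-macrophage marker plus the inflammatory program
  sets <- list(macro_program = c("CD14", truth$markers$inflammatory),
               flat = grep("^FILL", gene_symbols(run$norm), value = TRUE)[1:10])
  res <- compartment_score_compare(run$norm, ann, sets,
                                   c("macrophage", "tumor"))
  macro_row <- res[res$signature == "macro_program", ]
  expect_lt(macro_row$p_value, 0.05)
  expect_gt(macro_row$mean_first, macro_row$mean_second)
  expect_identical(res$adj_p, adjust_fdr(res$p_value))
})

test_that("identical compartments give p = 1 and missing compartments warn", {
  vals <- matrix(rep(1:4, 8), 4, 8,
                 dimnames = list(c("A", "B", "C", "D"), sprintf("c%d", 1:8)))
  m <- as_norm(vals, samples = rep(c("s1", "s2", "s3", "s4"), each = 2))
  ann <- data.frame(cell_id = sprintf("c%d", 1:8),
                    sample = rep(c("s1", "s2", "s3", "s4"), each = 2),
                    cell_type = rep(c("macrophage", "tumor"), 4))
  res <- compartment_score_compare(m, ann, list(s = c("A", "B")))
  expect_equal(res$p_value, 1)

  ann2 <- ann
  ann2$cell_type[ann2$sample == "s4" & ann2$cell_type == "tumor"] <-
    "macrophage"
  expect_warning(res2 <- compartment_score_compare(m, ann2,
                                                   list(s = c("A", "B"))),
                 "missing a compartment")
  expect_equal(res2$n_samples, 3)
})

test_that("Spearman test matches brute-force enumeration and monotone limits", {
  # strictly monotone pairs
  st <- spearman_test(1:6, c(2, 5, 9, 14, 20, 27))
  expect_equal(st$rho, 1)

  set.seed(14)
  x <- rnorm(5); y <- rnorm(5)
  st5 <- spearman_test(x, y)
  # oracle: all 120 rank permutations of y
  perms <- asplit(gliotam:::.permutations(5), 1)
  null_rho <- vapply(perms, function(p) cor(rank(x), p), numeric(1))
  p_oracle <- mean(abs(null_rho) >= abs(cor(x, y, method = "spearman")) - 1e-12)
  expect_equal(st5$p_value, p_oracle)
  expect_identical(st5$method, "exact enumeration")

  # invariance to monotone transforms of either side
  st_t <- spearman_test(exp(x), y^3 + 10 * y)
  expect_equal(st_t$rho, st5$rho)
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("crosstalk correlation recovers planted coupling and rejects tiny n", {
  run <- small_run()
  truth <- run$cohort$truth
  ann <- data.frame(cell_id = truth$cells$cell_id,
                    sample = truth$cells$sample,
                    cell_type = truth$cells$cell_type)
  res <- paired_crosstalk_correlation(run$norm, ann)
  expect_identical(res$n, length(unique(ann$sample)))
  # WT samples carry higher scavenger fractions and recruitment levels
  expect_gt(res$rho, 0)
  expect_identical(colnames(res$per_sample),
                   c("sample", "macrophage_mean", "tumor_score"))
  expect_error(paired_crosstalk_correlation(run$norm, ann[1:40, ],
                                            min_samples = 40),
               "samples with both")
  expect_error(paired_crosstalk_correlation(run$norm, ann,
                                            query_gene = "NOPE"), "absent")
})

test_that("BMDM/microglia contrast is antisymmetric and finds the planted lineage", {
  run <- small_run()
  truth <- run$cohort$truth
  bmdm <- c("CD163", "MSR1", "MRC1")
  microglia <- c("TMEM119", "P2RY12", "CX3CR1")
  scav <- scavenger_label(run)
  res <- bmdm_microglia_contrast(run$mac_norm, run$clusters$labels, scav,
                                 bmdm, microglia)
  expect_lt(res$p_value, 0.05)
  expect_gt(mean(res$per_subpop$contrast[res$per_subpop$is_scavenger]),
            mean(res$per_subpop$contrast[!res$per_subpop$is_scavenger]))
  # swapping the lineage sets negates the contrast exactly
  swapped <- bmdm_microglia_contrast(run$mac_norm, run$clusters$labels, scav,
                                     microglia, bmdm)
  expect_equal(swapped$per_subpop$contrast, -res$per_subpop$contrast)
  # refuse below the minimum number of subpopulations
  two <- run$mac_norm
  expect_error(bmdm_microglia_contrast(two, run$clusters$labels, scav,
                                       bmdm, microglia, min_subpops = 1000),
               "subpopulations")
})

test_that("GMT parsing resolves aliases and keeps set names", {
  path <- withr::local_tempfile(fileext = ".gmt")
  write_toy_gmt(path, list(setA = c("MARCO", "MCP-1"),
                           setB = c("SOX2", "CD14", "SDF-1")))
  sets <- read_gmt(path)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("MARCO", "CCL2"))
  expect_identical(sets$setB, c("SOX2", "CD14", "CXCL12"))
})

test_that("the recruitment panel carries the canonical 12 symbols", {
  p <- crosstalk_panel()
  expect_identical(length(p$symbols), 12L)
  expect_true(all(c("CSF1", "CSF2", "HGF", "CCL2", "MIF", "CXCL12",
                    "TGFB1", "TGFB2", "TGFB3", "IL10", "SPP1", "MFGE8")
                  %in% p$symbols))
})
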