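test_that("enrichment statistic is a difference of cluster means", {
  m <- as_norm(matrix(c(1, 1, 1, 1,
                        2, 2, 0, 0), 2, 4, byrow = TRUE,
                      dimnames = list(c("FLAT", "DIFF"), NULL)))
  labels <- c(1, 1, 2, 2)
  s <- enrichment_statistic(m, labels, 1)
  expect_equal(unname(s["FLAT"]), 0)
  expect_equal(unname(s["DIFF"]), 2)
  # swapping target negates the statistic with exactly two clusters
  expect_equal(enrichment_statistic(m, labels, 2), -s)
  expect_error(enrichment_statistic(m, labels, 3), "empty")
})

test_that("permutation p-values reproduce the panel-rank construction", {
  set.seed(2)
  stats <- stats::setNames(sample(rnorm(499)), sprintf("g%03d", 1:499))
  res <- empirical_perm_p(stats)
  expect_equal(res$perm_p[res$rank == 1], 2 / 499)
  expect_equal(res$perm_p[res$rank == 2], 4 / 499)
  expect_equal(round(res$perm_p[res$rank == 1], 3), 0.004)
  expect_equal(round(res$perm_p[res$rank == 2], 3), 0.008)
  # the median statistic of an odd-length list is capped at 1
  med_gene <- res$gene[res$statistic == median(stats)]
  expect_equal(res$perm_p[res$gene == med_gene], 1)
  # ranks are a permutation of 1..n
  expect_identical(sort(res$rank), 1:499)
  # admissible values only: multiples of 2/n capped at 1
  mult <- res$perm_p * 499 / 2
  expect_true(all(abs(mult - round(mult)) < 1e-9 | res$perm_p == 1))
})

test_that("permutation p multiset is symmetric under negating all statistics", {
  set.seed(3)
  stats <- stats::setNames(rnorm(51), sprintf("g%02d", 1:51))
  a <- empirical_perm_p(stats)
  b <- empirical_perm_p(-stats)
  expect_equal(sort(a$perm_p), sort(b$perm_p))
  # BH is monotone: adj_p ordering never inverts raw-p ordering
  o <- order(a$perm_p)
  expect_true(all(diff(a$adj_p[o]) >= -1e-12))
  # ties share the more conservative p
  tied <- stats::setNames(c(5, 5, 1, 0, -1), letters[1:5])
  res <- empirical_perm_p(tied)
  expect_equal(res$perm_p[res$gene %in% c("a", "b")], c(0.8, 0.8))
})

test_that("non-finite statistics are rejected by gene name", {
  expect_error(empirical_perm_p(c(a = 1, b = NaN)), "\\bb\\b")
})

test_that("chi-squared equals the textbook formula and printed-count tables", {
  oracle <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  hand <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  res <- contingency_chisq(hand)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$statistic, oracle(hand))
  expect_equal(res$p_value, pchisq(7.2, 1, lower.tail = FALSE))

  set.seed(6)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(contingency_chisq(tab)$statistic, oracle(tab))
  }

  equal <- matrix(10, 2, 2)
  res_eq <- contingency_chisq(equal)
  expect_equal(res_eq$statistic, 0)
  expect_equal(res_eq$p_value, 1)

  expect_error(contingency_chisq(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("the GBM/LGG nonzero-fraction contrast is highly significant", {
  gbm <- c(rep(1, 2092), rep(0, 17132 - 2092))
  lgg <- c(rep(1, 23), rep(0, 2199 - 23))
  res <- nonzero_fraction_test(gbm, lgg)
  expect_equal(unname(res$fractions), c(2092 / 17132, 23 / 2199))
  expect_equal(round(res$fractions[["A"]], 2), 0.12)
  expect_equal(round(res$fractions[["B"]], 2), 0.01)
  expect_lt(res$p_value, 0.001)
})

test_that("Mann-Whitney matches exhaustive enumeration at small n", {
  a <- c(3, 4, 5); b <- c(0, 0, 1)
  res <- group_mean_compare(a, b)
  # brute-force oracle over all C(6,3) = 20 group assignments
  pooled <- c(a, b); r <- rank(pooled)
  assigns <- utils::combn(6, 3)
  u_null <- apply(assigns, 2, function(i) sum(r[i]) - 6)
  u_obs <- sum(r[1:3]) - 6
  p_oracle <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
  expect_equal(res$U, u_obs)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$fold_ratio, mean(a) / mean(b))
  expect_identical(res$method, "exact enumeration")
  # no-ties case agrees with wilcox.test's exact distribution
  x <- c(1.2, 3.4, 2.2, 8); y <- c(0.1, 0.5, 4.4)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(group_mean_compare(x, y)$p_value, wt$p.value)
})

test_that("identical groups yield p = 1 and fold handles zero means", {
  res <- group_mean_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_true(is.infinite(group_mean_compare(c(1, 2), c(0, 0))$fold_ratio))
  expect_error(group_mean_compare(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis equals direct rank-formula evaluation", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- grouped_expression_test(groups)
  # hand evaluation: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), no ties
  Rsums <- c(1 + 2, 3 + 4, 5 + 6)
  H_hand <- 12 / (6 * 7) * sum(Rsums^2 / 2) - 3 * 7
  expect_equal(res$H, H_hand)
  expect_equal(res$H, 32 / 7)

  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res0 <- grouped_expression_test(same)
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)
  expect_error(grouped_expression_test(list(1:2, 3:4)), "group_mean_compare")
})

test_that("Kruskal-Wallis p is calibrated under label permutation", {
  set.seed(44)
  ps <- replicate(60, {
    v <- rnorm(18)
    grouped_expression_test(split(v, rep(1:3, each = 6)))$p_value
  })
  # the chi-squared approximation at n = 18 is mildly discrete; KS ties ok
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("normalized dispersion flags a planted high-variance gene", {
  set.seed(9)
  n_genes <- 60; n_cells <- 200
  mu <- rep(5, n_genes)
  x <- matrix(rpois(n_genes * n_cells, mu), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("c%03d", 1:n_cells)))
  # inflate variance of g01 at fixed mean: mixture of 0 and 2*mu
  x["g01", ] <- rpois(n_cells, 10) * rbinom(n_cells, 1, 0.5) * 2
  m <- as_counts(x, rep(c("b1", "b2"), each = n_cells / 2))
  res <- suppressWarnings(normalized_dispersion(m))
  expect_identical(res$gene[res$rank == 1], "g01")
  expect_equal(res$perm_p[res$rank == 1], 2 / nrow(res))
})

test_that("single-batch dispersion equals the per-batch z-score and flat input is 0", {
  set.seed(10)
  x <- matrix(rpois(40 * 100, 5), 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:100)))
  one <- suppressWarnings(
    normalized_dispersion(as_counts(x, rep("b1", 100))))
  xx <- cbind(x, x)
  colnames(xx) <- sprintf("c%03d", seq_len(200))
  two_same <- suppressWarnings(
    normalized_dispersion(as_counts(xx, rep(c("b1", "b2"), each = 100))))
  # duplicating the batch leaves the combined z-score unchanged
  expect_equal(stats::setNames(two_same$norm_dispersion, two_same$gene),
               stats::setNames(one$norm_dispersion, one$gene)[two_same$gene])

  flat <- matrix(rep(c(1, 3), 50), nrow = 2, byrow = FALSE,
                 dimnames = list(c("gA", "gB"), sprintf("c%02d", 1:50)))
  # both genes constant across cells: variance 0, dispersion 0, z 0
  res <- suppressWarnings(normalized_dispersion(as_counts(flat)))
  expect_true(all(res$norm_dispersion == 0))
})

test_that("leave-one-out keeps a dominant planted marker at rank 1", {
  run <- small_run()
  loo <- leave_one_out_rank(run$mac_norm, "MARCO", run$ecfg)
  expect_identical(loo$rank, 1L)
  expect_equal(loo$perm_p, 2 / nrow(run$mac_norm$values))
  expect_error(leave_one_out_rank(run$mac_norm, "NOT_A_GENE", run$ecfg),
               "absent")
  tiny <- as_norm(matrix(runif(2 * 30), 2, 30,
                         dimnames = list(c("A", "B"), NULL)))
  expect_error(leave_one_out_rank(tiny, "A"), "fewer than 2 genes")
})
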