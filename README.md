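# gliotam

Tumor-associated macrophage (TAM) subtyping for multi-sample glioma
single-cell RNA-seq cohorts, with matched bulk survival analysis.

Glioblastomas are heavily infiltrated by macrophages whose phenotypes span a
spectrum from inflammatory to pro-tumor. `gliotam` implements a complete,
reproducible pipeline for finding and characterizing a scavenger-receptor
(MARCO-like) macrophage subpopulation in pooled UMI count matrices:

1. **Preprocessing** — mitochondrial/ribosomal gene removal, multi-sample
   merging on the gene intersection (zero-total genes dropped), per-cell
   `log2(1 + TPK)` normalization (TPK = transcripts per thousand, i.e.
   counts rescaled so each cell sums to 1000), and restriction to an immune
   gene panel (e.g. the LM22 list) to blunt batch effects.
2. **Embedding and typing** — PCA to 5% of the gene count, UMAP to 2-D,
   marker-based cell typing (CD14 → macrophage, CD3D/CD3E/CD3G → T cell,
   SOX2 → tumor).
3. **Macrophage clustering** — the macrophage compartment is re-embedded
   and split by k-means on the 2-D embedding; k is selected by the mean
   silhouette width over k = 2..6.
4. **Marker statistics** — per-cluster enrichment (difference of cluster
   means of normalized expression) with an empirical exact permutation
   p-value against the panel-wide statistic distribution:
   `p = 2 · min(r_hi, r_lo) / n`, self-inclusive, capped at 1 (so the top
   gene of a 499-gene panel gets p = 2/499 ≈ 0.004). Plus leave-one-out
   rank robustness, nonzero-fraction chi-squared contrasts, Mann-Whitney /
   Kruskal-Wallis group comparisons, and batch-corrected normalized
   dispersion.
5. **Signature scoring** — Patel-style per-cell scores (mean of
   gene-centered normalized expression over a set), compartment
   comparisons, BMDM-vs-microglia lineage contrasts, and paired
   macrophage–tumor Spearman correlation against a 12-symbol
   recruitment-factor panel (CSF1, CSF2, HGF, CCL2, MIF, CXCL12,
   TGFB1/2/3, IL10, SPP1, MFGE8).
6. **GSEA** — from-scratch weighted Kolmogorov–Smirnov running-sum
   enrichment with a continuous phenotype (e.g. MARCO expression), Pearson
   correlation ranking, weight p = 1, phenotype permutation (1000
   iterations by default), sign-stratified NES and FDR q.
7. **Survival** — per-cohort log + Z normalization of bulk expression,
   median dichotomization with Kaplan–Meier/log-rank, and Cox proportional
   hazards (Efron ties, Wald p), univariable or confounder-adjusted.

Because the underlying patient data cannot ship with the package, a
first-class synthetic-cohort generator (`generate_cohort()`,
`generate_bulk_survival()`) plants the structure every stage assumes:
discrete cell types, two opposed macrophage programs whose prevalence is
gated by sample-level IDH1 status, tumor-cell recruitment factors coupled
to the scavenger fraction, and exponential survival under proportional
hazards.

## Worked example

```r
library(gliotam)

cfg <- run_config(simulate = cohort_config(seed = 101),
                  stages = c("preprocess", "cluster", "markers", "scores"),
                  umap_seed = 102, kmeans_seed = 103)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
#> gliotam run report
#>   simulate: 1.8s preprocess: 0.4s embed: 14.8s macro_embed: 3.5s
#>   macro_cluster: 2.5s markers: 0.0s scores: 0.0s
#>   selected k = 2 (mean silhouette 0.870)
#>   scavenger cluster: 2
#>   cross-talk Spearman rho = 0.708 (p = 0.0004746, n = 20)

head(report$marker_tables[[paste0("cluster", report$scavenger_cluster)]], 3)
#>     gene statistic rank     perm_p adj_p
#> 1  MARCO  3.243316    1 0.01190476     1
#> 2   MRC1  2.406836    2 0.02380952     1
#> 3 LGALS3  2.398759    3 0.03571429     1
```

The silhouette selection lands on k = 2 macrophage subpopulations; the
planted scavenger marker (MARCO) tops the scavenger cluster's marker table
with the minimal attainable permutation p (2 / panel size), and the
per-sample macrophage MARCO mean correlates positively with the tumor-cell
recruitment-factor score, reflecting the generator's cross-talk coupling.

A bulk survival run:

```r
bulk <- generate_bulk_survival(survival_sim_config(n_patients = 400,
                                                   true_log_hr = log(1.8),
                                                   seed = 27))
res <- survival_analysis(list(synthetic = bulk$expression), bulk$clinical)
res$cox_univariable
#>      covariate      coef      HR         se        z       wald_p
#> 1 expression_z 0.5018594 1.65179 0.05868343 8.551977 1.209975e-17
```

A thin command-line wrapper lives at `inst/cli/gliotam-cli.R`
(subcommands `simulate`, `run-all`, `survival`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gliotam",
                               load_package = "installed")'
```
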