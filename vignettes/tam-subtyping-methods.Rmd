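---
title: "Methods: macrophage subtyping in glioma single-cell cohorts"
author: "gliotam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macrophage subtyping in glioma single-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures `gliotam` implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-cohort generator does and does not emulate, and the
design choices made where the methodology was genuinely open.

## The analysis problem

Glioma single-cell UMI cohorts pooled from many patients and platforms
carry strong batch structure. The pipeline's goal is to isolate the
macrophage compartment, split it into subpopulations, and characterize the
subpopulation carrying a scavenger-receptor program (MARCO and allied
genes): its defining markers, its transcriptional programs, its coupling to
tumor-cell recruitment-factor expression across samples, and the prognostic
value of its marker in bulk cohorts.

## Preprocessing

* **Mito/ribo filtering.** Genes with symbols matching the prefixes `MT-`,
  `MRPL`, `MRPS`, `RPL`, `RPS` (case-insensitive) are removed. The prefix
  rule is the community convention for "mitochondrial and ribosomal
  proteins"; no expression threshold is involved.
* **Merging.** Per-sample matrices are merged on the *intersection* of
  their gene sets (first input's order), cells concatenated in input
  order; genes with zero total count in the merged matrix are discarded.
  Cohorts of different diagnoses (e.g. GBM vs LGG) are merged separately.
* **Normalization.** `log2(1 + TPK)` where TPK rescales each cell to a
  total of 1000 counts. TPK-on-UMIs is a pure per-cell scaling, so the
  transform maps zero counts to exactly zero (sparsity preserved) and is
  invariant to scalar multiplication of a cell's counts. Cells with zero
  total are an error, named explicitly.
* **Panel restriction.** Normalization happens *before* panel restriction,
  so per-cell totals reflect all retained genes; restricting first would
  change every TPK denominator. The panel (e.g. the LM22 immune list) is
  the pipeline's only batch mitigation: restricting to immune-discriminant
  genes suppresses platform- and tumor-intrinsic axes of variation.

## Embedding, typing, clustering

* **PCA** keeps `round(0.05 × n_genes)` components (round-half-up; clipped
  to `[1, min(cells, genes) − 1]`). For a 499-gene panel that is 25
  components.
* **UMAP** (uwot) runs with library defaults apart from an explicit seed
  and single-threaded SGD, making coordinates bit-reproducible. The
  neighborhood size (default 15) must be below the cell count; the error
  message suggests shrinking it for tiny inputs.
* **Cell typing** over-clusters the 2-D embedding (k-means, 8 centers by
  default) and labels each coarse cluster by the marker family with the
  highest mean z-scored expression — CD14 (macrophage), CD3D/CD3E/CD3G
  (T cell), SOX2 (tumor) — leaving clusters with no positive family mean
  unassigned. Cluster-level voting was chosen over per-cell thresholds
  because a manual-typing rule is not otherwise pinned down, and voting is
  robust to dropout in individual cells.
* **Macrophage clustering.** The macrophage subset is *re-processed* with
  the same PCA→UMAP procedure (not sliced from the global embedding), and
  k-means is applied to the 2-D macrophage embedding — deliberately taking
  the published procedure at face value rather than clustering in PCA
  space. k is selected by mean silhouette width over k = 2..6. For more
  than 4000 cells the silhouette is evaluated on a fixed-seed 4000-cell
  subsample because the exact computation needs an O(n²) distance matrix;
  labels always come from the full k-means. Infeasible k (more centers
  than distinct points) report `NA` and are skipped.

## Marker statistics

* **Enrichment statistic**: difference between a gene's mean normalized
  expression inside the target cluster and its mean in all other
  macrophages. "Top enriched gene" = rank 1 by this statistic.
* **Empirical exact permutation test.** The panel itself provides the
  null: for gene *g* with statistic *s*, `r_hi` counts panel genes with
  statistic ≥ *s* and `r_lo` those with ≤ *s* (self included), and
  `p = min(1, 2·min(r_hi, r_lo)/n)`. This self-inclusive two-sided
  construction is the one consistent with the printed values 2/499 ≈ 0.004
  for a top-ranked gene and 4/499 ≈ 0.008 for the runner-up. Ties share
  the larger (conservative) p. Note the structural consequence that BH
  adjustment of a full panel of such p-values saturates near 1 — the
  sorted p-values are ≈ 2i/n, so every BH ratio is ≈ 2; the adjusted
  column is reported anyway for uniformity.
* **Leave-one-out robustness** re-runs PCA→UMAP→k-means *without* the query
  gene, then ranks the full panel (query included) against the new
  clustering, reporting the query's rank in the cluster where it is most
  enriched.
* **Nonzero-fraction contrast**: 2×2 Pearson chi-squared without Yates
  correction (all intended uses have large counts), 1 df. The same
  operation serves proliferation-marker co-expression tables.
* **Two-group comparisons** use the two-sided Mann-Whitney U. p is exact —
  by exhaustive enumeration of group assignments, which handles ties
  correctly — whenever both groups have ≤ 20 members *and* the number of
  assignments is ≤ 2·10⁵; otherwise the normal approximation with tie
  correction. (Enumeration for two groups of 20 would need ~10¹¹
  assignments, so a pure size rule cannot deliver exactness.)
* **≥3 groups**: Kruskal-Wallis with tie correction.
* **Normalized dispersion** (marker-utility analysis): per batch, each
  gene's dispersion (variance/mean) is z-scored within 20 equal-count bins
  of the per-gene mean (bins with < 2 genes merge into a neighbor); the
  combined statistic is the mean per-batch z-score over batches where the
  gene is expressed, and p-values come from the same panel-rank
  permutation test. This reproduces the binned dispersion-norm flavor of
  standard highly-variable-gene selection with batch correction.

## Signature scores and cross-talk

The per-cell score of a gene set is the mean, over set genes present in
the matrix, of the gene's normalized expression centered across the scored
cell population (macrophages or tumor cells — recorded in output
metadata). No control-gene-set subtraction is applied: this is the minimal
faithful form of the average-relative-expression score, and it makes the
score exactly invariant to per-gene constants and equivariant under global
scaling. Scores therefore average to (numerically) zero over the scored
population.

Cross-talk analysis summarizes, per sample, the mean normalized MARCO
expression over macrophages and the mean recruitment-factor signature
score over tumor cells, then correlates the two across samples by
Spearman's rho. The recruitment panel holds 12 symbols (the 10 classical
factors with TGF-β expanded to TGFB1/2/3); protein-name aliases (MCP-1,
SDF-1, Ki-67) are resolved through a user-editable table shipped with the
package. Spearman p is exact by enumeration of rank permutations for
n ≤ 8 and uses the t approximation above that.

## GSEA

The enrichment score is the signed maximum deviation of the weighted
running sum: hits advance by `|r|^p / Σ_set |r|^p` (default weight p = 1,
metric r = Pearson correlation of the gene with the per-cell phenotype),
misses retreat by `1/(N − set size)`. Metric ties are broken by gene
symbol; an exact magnitude tie between the positive and negative extremum
resolves to the positive side (tolerance 1e-12).

The null is *phenotype permutation* — the phenotype vector is shuffled
across cells and the entire ranking and scoring recomputed — which
preserves gene-gene correlation. Nominal p is sign-stratified with add-one
smoothing, `(1 + #{null ES, same sign, |ES| ≥ |obs|}) / (1 + #{null ES of
that sign})`, so p is never exactly zero (a deliberate divergence from
clients that print 0). NES divides ES by the mean |null ES| of its sign;
FDR q is the standard sign-stratified ratio of pooled-null to observed
tail fractions, clipped to [0, 1].

One consequence worth knowing: because phenotype permutation preserves
gene-gene correlation, a set of mutually near-affine genes can re-attain
its observed ES in a permutation whenever the set's shared correlation
happens to lead the ranking. The floor `1/(1 + n_same_sign)` is therefore
attained only when the observed ES strictly beats every null, which a
coherent set is not guaranteed to do.

## Survival

Each bulk cohort is log2-transformed (unless flagged as already
log-scale — the microarray vs RNA-seq dialect is an explicit flag, never a
guess) and z-scored per gene *within* its cohort before concatenation, so
no cross-cohort location/scale shift survives. The worked consequence:
values {1, 2, 4, 8} normalize to approximately (−1.162, −0.387, 0.387,
1.162).

Dichotomization splits strictly above the median into `high`; ties at the
median go to `low` (the choice is arbitrary but visible — group sizes are
always attached). Kaplan–Meier curves come from the product-limit
estimator with a two-group log-rank test (1 df); survival probabilities at
requested horizons (e.g. 2-/5-year rates) are extracted from the fitted
curves, with time units taken as given per cohort. Cox models use Efron
tie handling and report Wald p from the observed information; monotone
likelihood (perfect separation) and collinear covariates produce
instructive errors rather than divergent estimates.

## The synthetic cohort generator

The generator is the package's stand-in for a multi-sample patient cohort
and defines the conditions under which the pipeline's recovery properties
are tested:

* **Counts** are negative binomial in the mean/size parameterization
  (default size 2). No explicit zero-inflation: at single-cell means the NB
  already produces realistic sparsity.
* **Library sizes** are log-normal per cell (σ = 0.5, mean 1) around
  `library_size_mean` (default 2000 UMIs).
* **Cell types** (tumor 0.5 / T cell 0.2 / macrophage 0.3 by default) are
  sampled per cell; macrophages carry one of two opposed programs. The
  scavenger program (MARCO, CD163, MSR1, MRC1, CHIT1, GPNMB, LGALS3,
  FABP5, CSTB, ANXA2) and the inflammatory program (CCL4, IL1B, TMEM119,
  CCL3, TNF, CXCL8, IL1A, P2RY12, CX3CR1, NFKBIA) are elevated by
  `marker_log_fold` (default 3 log2 units) in their home subpopulation.
  Each program has a dominant defining marker — MARCO and CCL4 carry one
  extra log2 unit, IL1B half a unit — because the emulated biology has an
  unambiguous top gene on each side, and rank-recovery claims are
  meaningless if all ten program genes are exchangeable.
* **Genotype gating.** Each sample is IDH1-wild-type or mutated (20%
  mutated by default); its true scavenger fraction is Beta-distributed
  around the status-level mean (WT 0.3, mut 0.0 by default; a configured 0
  is exactly 0). Real gene symbols are used throughout so downstream
  modules run unmodified.
* **Cross-talk.** The recruitment-factor log2 fold in a sample's tumor
  cells is `marker_log_fold × scavenger_fraction` plus Gaussian noise
  scaled by `1 − crosstalk_coupling` (default coupling 0.7), making the
  sample-level correlation rise monotonically with the coupling.
* **Survival.** Event times are exponential with hazard
  `baseline × exp(log HR × z)` for a standard-normal expression covariate
  z, independent exponential censoring; the bulk expression table encodes
  z as `2^(8 + z)` in the query gene so the normalization stage recovers
  it.

Default scale is 20 samples × 500 cells — small enough that the full
pipeline (two UMAP embeddings included) runs in well under a minute,
large enough for the planted structure to dominate sampling noise. The
generator does **not** emulate doublets, ambient RNA, platform-specific
dropout curves, batch effects beyond library size, or spatial structure;
passing recovery tests on it demonstrates the pipeline's correctness on
its assumed generative model, not robustness to every artifact of real
tissue data.

## Numerical choices and degenerate inputs

* Component-count rounding is round-half-up (0.05 × 499 → 25).
* All stochastic stages (simulation, UMAP, k-means, GSEA permutation) take
  explicit seeds recorded in the provenance manifest; two runs with one
  config are byte-identical.
* k-means uses 10 restarts per k; silhouette subsampling is capped at 4000
  cells (above).
* Zero-variance genes are excluded from correlation ranking with a logged
  count; constant phenotypes, empty clusters, all-zero table margins,
  zero-variance genes within a survival cohort, and sets covering a whole
  ranked list are errors, not silent results.
* The silhouette of the *optimal* 2-split of a single Gaussian blob is
  ≈ 0.4 — not near 0 — a property of the statistic worth remembering when
  reading model-selection tables; the selection is trustworthy only as an
  argmax over k, and the package also reports the full silhouette table.

## Problem sizes used in the shipped checks

Unit and property tests run on cohorts of 4–8 samples × 50–150 cells;
recovery checks at the default 20 × 500 scale; Cox recovery on 5000
synthetic patients; permutation calibration on 40–50 seed ensembles with
small matrices. These sizes were chosen so the planted effects are
comfortably detectable while the full suite stays fast.

## Known limitations

* No graph-based clustering, data integration, ambient-RNA or doublet
  handling; the panel restriction is the only batch mitigation.
* The permutation marker test measures a gene's standing *within a panel*,
  not differential expression against a cell-level null; its p-values are
  bounded below by 2/n.
* GSEA q-values at few permutations are unstable (a warning fires below
  10); the default is 1000.
* The Patel-style score omits control-gene-set correction; scores are
  comparable within the scored population only.
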