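# Gene set enrichment analysis with a continuous per-cell phenotype:
# Pearson-correlation gene ranking, weighted Kolmogorov-Smirnov running-sum
# enrichment score, phenotype-permutation null, sign-stratified NES and FDR.

#' GSEA configuration
#'
#' @param weight_exponent weight on |metric| in the running sum (default 1,
#'   the standard weighting).
#' @param n_permutations phenotype permutations for the null (default 1000).
#' @param seed integer seed for the permutations.
#' @return a `gsea_config` list.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000,
                        seed = 1L) {
  if (weight_exponent < 0) stop("weight_exponent must be >= 0")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (n_permutations < 10)
    warning("fewer than 10 permutations: p and q estimates are unstable")
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "gsea_config")
}

#' Rank genes by Pearson correlation with a continuous phenotype
#'
#' Genes are sorted by descending Pearson r with the per-cell phenotype
#' (e.g. MARCO expression across macrophages); zero-variance genes are
#' excluded with a message, and metric ties are broken by gene symbol for
#' reproducibility.
#'
#' @param m a [tam_norm()] (genes x cells).
#' @param phenotype numeric vector, one value per cell; must vary.
#' @param quiet suppress the excluded-gene message.
#' @return named numeric vector of correlations, sorted descending.
#' @export
rank_by_correlation <- function(m, phenotype, quiet = TRUE) {
  stopifnot(inherits(m, "tam_norm"))
  if (length(phenotype) != ncol(m$values))
    stop("phenotype must have one value per cell")
  if (sd(phenotype) == 0) stop("constant phenotype: correlation undefined")
  r <- .gene_phenotype_cor(m$values, phenotype)
  drop <- !is.finite(r)
  if (any(drop) && !quiet)
    message(sum(drop), " zero-variance gene(s) excluded from ranking")
  r <- r[!drop]
  r[order(-r, names(r))]
}

# Pearson r of every row of a (sparse) matrix with a vector, in one pass
.gene_phenotype_cor <- function(x, y) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mu <- rowMeans(x)
  cross <- as.numeric(x %*% yc)           # sum_i x_gi * yc_i (mean(yc)=0)
  sx <- sqrt(rowSums(x^2) - n * mu^2)
  r <- cross / (sx * sy)
  names(r) <- rownames(x)
  r[sx == 0] <- NA_real_
  r
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at set genes the hit curve increments by
#' `|metric|^w / sum_set |metric|^w`, elsewhere the miss curve increments by
#' `1/(N - set size)`. The enrichment score is the signed maximum deviation
#' of hit minus miss; the leading edge is the set genes at or before the
#' extremum (after it, for negative scores).
#'
#' @param metric named numeric vector of ranking metrics, sorted descending
#'   (from [rank_by_correlation()]).
#' @param set character vector of member symbols (at least one in the list,
#'   and not the whole list).
#' @param weight weight exponent (default 1).
#' @return list: `ES`, `running` (the full running sum), `leading_edge`,
#'   `n_hits`.
#' @export
enrichment_score <- function(metric, set, weight = 1) {
  genes <- names(metric)
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  if (nh == 0) stop("no set gene in the ranked list")
  if (nh == N) stop("set covers the whole list: miss increment undefined")
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  steps <- ifelse(hit,
                  if (denom > 0) w / denom else 1 / nh,
                  -1 / (N - nh))
  if (denom == 0) steps[!hit] <- -1 / (N - nh)  # degenerate all-zero metric
  running <- cumsum(steps)
  hi <- max(running); lo <- min(running)
  # signed maximum deviation; a magnitude tie resolves to the positive side
  if (hi >= -lo - 1e-12) {
    es <- hi; i <- which.max(running)
  } else {
    es <- lo; i <- which.min(running)
  }
  le <- if (es >= 0) genes[hit & seq_len(N) <= i] else
    genes[hit & seq_len(N) >= i]
  list(ES = unname(es), running = unname(running), leading_edge = le,
       n_hits = nh)
}

#' GSEA with phenotype permutation
#'
#' For each permutation the phenotype is shuffled across cells and the full
#' ranking + enrichment score pipeline is recomputed for every set. Nominal
#' p-values are sign-stratified with add-one smoothing,
#' `(1 + #{null ES of same sign with |ES| >= |obs|}) / (1 + #{null ES of
#' that sign})`; NES divides each ES by the mean |null ES| of its sign
#' stratum; FDR q follows the standard sign-stratified ratio of tail
#' fractions of the pooled normalized null versus the observed NES,
#' clipped to \[0, 1\].
#'
#' @param m a [tam_norm()] over the phenotype's cells (e.g. macrophages).
#' @param phenotype numeric per-cell phenotype (e.g. MARCO expression).
#' @param sets named list of gene sets.
#' @param cfg a [gsea_config()].
#' @return data.frame (`enrichment_record`) sorted by descending ES:
#'   set, size (genes in list), ES, NES, nominal_p, fdr_q,
#'   leading_edge (comma-joined symbols).
#' @export
phenotype_permutation <- function(m, phenotype, sets,
                                  cfg = gsea_config()) {
  stopifnot(inherits(m, "tam_norm"))
  if (length(sets) == 0) stop("need at least one gene set")
  obs_rank <- rank_by_correlation(m, phenotype)
  obs <- lapply(sets, function(s)
    enrichment_score(obs_rank, s, cfg$weight_exponent))
  obs_es <- vapply(obs, `[[`, numeric(1), "ES")

  set.seed(cfg$seed)
  null_es <- matrix(NA_real_, nrow = length(sets), ncol = cfg$n_permutations,
                    dimnames = list(names(sets), NULL))
  for (p in seq_len(cfg$n_permutations)) {
    perm <- sample(phenotype)
    r <- rank_by_correlation(m, perm)
    null_es[, p] <- vapply(sets, function(s)
      enrichment_score(r, s, cfg$weight_exponent)$ES, numeric(1))
  }

  nominal_p <- vapply(seq_along(sets), function(i) {
    nulls <- null_es[i, ]
    same <- if (obs_es[i] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    (1 + sum(abs(same) >= abs(obs_es[i]))) / (1 + length(same))
  }, numeric(1))

  # sign-stratified normalization: each ES divided by the same-set mean
  # |null ES| of its sign
  norm_one <- function(es, nulls) {
    same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    denom <- mean(abs(same))
    if (!is.finite(denom) || denom == 0) return(NA_real_)
    es / denom
  }
  nes <- vapply(seq_along(sets), function(i)
    norm_one(obs_es[i], null_es[i, ]), numeric(1))
  null_nes <- t(vapply(seq_along(sets), function(i) {
    vapply(null_es[i, ], norm_one, numeric(1), nulls = null_es[i, ])
  }, numeric(cfg$n_permutations)))

  pool <- as.numeric(null_nes)
  pool <- pool[is.finite(pool)]
  fdr_q <- vapply(seq_along(sets), function(i) {
    v <- nes[i]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      null_tail <- sum(pool >= v) / max(1, sum(pool >= 0))
      obs_tail <- sum(nes >= v, na.rm = TRUE) /
        max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      null_tail <- sum(pool <= v) / max(1, sum(pool < 0))
      obs_tail <- sum(nes <= v, na.rm = TRUE) /
        max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, max(0, null_tail / max(obs_tail, .Machine$double.eps)))
  }, numeric(1))

  res <- data.frame(
    set = names(sets),
    size = vapply(obs, `[[`, numeric(1), "n_hits"),
    ES = unname(obs_es),
    NES = nes,
    nominal_p = nominal_p,
    fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$ES), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_record", "data.frame")
  res
}
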