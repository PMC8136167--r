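# Bulk-expression survival analysis: per-cohort log + Z normalization,
# median dichotomization, Kaplan-Meier with log-rank, and Cox proportional
# hazards (univariable and covariate-adjusted, Efron ties, Wald p).

#' Per-cohort log + Z normalization of bulk expression
#'
#' Each cohort is normalized independently — log2 transform (skipped for
#' cohorts flagged as already log-scale) followed by a per-gene z-score —
#' then the cohorts are concatenated, so no cross-cohort location or scale
#' shift survives.
#'
#' @param cohorts named list of numeric matrices (genes x samples); sample
#'   ids must be unique across cohorts.
#' @param already_log logical, one per cohort (recycled), flagging inputs
#'   that are already log-scale.
#' @return numeric matrix of z-scores (genes x all samples) on the gene
#'   intersection of the cohorts.
#' @export
normalize_cohorts <- function(cohorts, already_log = FALSE) {
  if (is.matrix(cohorts)) cohorts <- list(cohort1 = cohorts)
  already_log <- rep_len(already_log, length(cohorts))
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(common) == 0) stop("no gene shared across cohorts")
  norm <- lapply(seq_along(cohorts), function(i) {
    x <- as.matrix(cohorts[[i]])[common, , drop = FALSE]
    if (!already_log[i]) {
      if (any(x <= 0))
        stop(sprintf("cohort %s: nonpositive values; pass already_log=TRUE %s",
                     names(cohorts)[i], "or pre-offset the data"))
      x <- log2(x)
    }
    s <- apply(x, 1, sd)
    if (any(s == 0))
      stop(sprintf("cohort %s: zero-variance gene(s): %s",
                   names(cohorts)[i],
                   paste(head(common[s == 0], 5), collapse = ", ")))
    (x - rowMeans(x)) / s
  })
  do.call(cbind, norm)
}

#' Median dichotomization into high/low groups
#'
#' Values strictly above the median are `high`; values at or below it are
#' `low` (ties at the median deliberately fall to `low`, and group sizes are
#' attached so the choice is visible).
#'
#' @param z named numeric vector (>= 2 values, not all identical).
#' @return factor of `high`/`low` labels with a `sizes` attribute.
#' @export
dichotomize_median <- function(z) {
  if (length(z) < 2) stop("need at least 2 samples")
  if (length(unique(z)) == 1) stop("all values identical: no median split")
  med <- median(z)
  g <- factor(ifelse(z > med, "high", "low"), levels = c("low", "high"))
  names(g) <- names(z)
  attr(g, "sizes") <- table(g)
  g
}

#' Kaplan-Meier curves with a two-group log-rank test
#'
#' Product-limit estimates per group plus the two-group log-rank chi-squared
#' (1 df). A group with zero events still enters the test, with a warning.
#'
#' @param records data.frame with columns `time` (>= 0) and `event`
#'   (logical or 0/1).
#' @param groups factor/vector of two group labels, one per record.
#' @return list (`km_estimate`): `fit` (a `survival::survfit` object),
#'   `logrank_chisq`, `p_value`, `groups` (sizes), `survival_at(times)`
#'   helper returning per-group survival probabilities.
#' @export
km_logrank <- function(records, groups) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("negative follow-up time")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  if (any(tapply(records$event, groups, sum) == 0))
    warning("a group has zero events; log-rank still computed")
  d <- data.frame(time = records$time, event = as.integer(records$event),
                  group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  survival_at <- function(times) {
    s <- summary(fit, times = times, extend = TRUE)
    split(setNames(s$surv, s$time), s$strata)
  }
  structure(list(fit = fit, logrank_chisq = unname(lr$chisq), p_value = p,
                 groups = table(groups), survival_at = survival_at),
            class = "km_estimate")
}

#' Cox proportional-hazards fit (Efron ties, Wald p)
#'
#' Univariable or covariate-adjusted partial-likelihood fit; coefficients
#' are reported with standard errors from the observed information and Wald
#' p-values, plus hazard ratios.
#'
#' @param records data.frame with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names; the first
#'   is conventionally the expression z-score of the query gene.
#' @return data.frame (`cox_fit`): covariate, coef (log HR), HR, se, z,
#'   wald_p; plus attributes `n` and `n_events`.
#' @export
cox_fit <- function(records, covariates) {
  stopifnot(all(c("time", "event") %in% names(records)))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0)
    stop("covariate(s) absent from records: ",
         paste(missing_cov, collapse = ", "))
  if (sum(records$event) < 1) stop("need at least one observed event")
  x <- records[, covariates, drop = FALSE]
  num <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) > 1 && qr(as.matrix(num))$rank < ncol(num))
    stop("collinear covariates: ", paste(colnames(num), collapse = ", "))
  fml <- stats::as.formula(paste("survival::Surv(time, as.integer(event)) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop(paste0("monotone-likelihood separation: a covariate perfectly ",
                    "orders the events; remove or coarsen it"))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  out <- data.frame(covariate = rownames(s),
                    coef = s[, "coef"],
                    HR = s[, "exp(coef)"],
                    se = s[, "se(coef)"],
                    z = s[, "z"],
                    wald_p = s[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Read a clinical table
#'
#' CSV with columns sample, time, event and optionally age, mgmt, idh1,
#' subtype.
#'
#' @param path CSV path.
#' @return data.frame with `event` coerced to logical.
#' @export
read_clinical <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(d)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  d$event <- as.logical(d$event)
  d
}

#' Survival analysis of a query gene in bulk cohorts
#'
#' Normalizes the cohorts ([normalize_cohorts()]), joins the query gene's
#' z-scores to the clinical table, and runs both analyses: median
#' dichotomization + KM/log-rank, and a Cox fit on the continuous z-score
#' (optionally adjusted for confounders).
#'
#' @param cohorts named list of expression matrices (genes x samples).
#' @param clinical data.frame from [read_clinical()].
#' @param gene query gene symbol.
#' @param already_log per-cohort log-scale flags.
#' @param adjust extra covariate names in `clinical` for a multivariable
#'   fit (e.g. c("age", "mgmt")); NULL for univariable only.
#' @return list: `km` ([km_logrank()] result), `cox_univariable`,
#'   `cox_adjusted` (NULL unless `adjust`), `groups`, `n`.
#' @export
survival_analysis <- function(cohorts, clinical, gene = "MARCO",
                              already_log = FALSE, adjust = NULL) {
  z <- normalize_cohorts(cohorts, already_log)
  if (!gene %in% rownames(z)) stop("gene ", gene, " absent from cohorts")
  common <- intersect(colnames(z), clinical$sample)
  if (length(common) < 2) stop("fewer than 2 samples with clinical data")
  clin <- clinical[match(common, clinical$sample), ]
  clin$expression_z <- as.numeric(z[gene, common])
  groups <- dichotomize_median(setNames(clin$expression_z, clin$sample))
  km <- km_logrank(clin, groups)
  cox_uni <- cox_fit(clin, "expression_z")
  cox_adj <- if (!is.null(adjust))
    cox_fit(clin, c("expression_z", adjust)) else NULL
  list(km = km, cox_univariable = cox_uni, cox_adjusted = cox_adj,
       groups = groups, n = length(common))
}
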