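#' Dichotomize toxicity grades into cases and controls
#'
#' Neutropenia cases are grade >= 3 (controls 0-2); neuropathy cases are
#' grade >= 2 (controls 0-1). Missing grades stay `NA` and their count is
#' attached as attribute `n_missing`.
#'
#' @param grades Integer grades, 0-4 for neutropenia or 0-3 for neuropathy;
#'   `NA` allowed.
#' @param phenotype `"neutropenia"` or `"neuropathy"`.
#' @return Integer 0/1 case indicator (with `NA` preserved) and attribute
#'   `n_missing`.
#' @export
dichotomize <- function(grades, phenotype = c("neutropenia", "neuropathy")) {
  phenotype <- match.arg(phenotype)
  max_grade <- switch(phenotype, neutropenia = 4L, neuropathy = 3L)
  ok <- is.na(grades) | (grades >= 0 & grades <= max_grade)
  if (!all(ok)) {
    stop("grade out of range 0-", max_grade, " for ", phenotype, ": ",
         paste(unique(grades[!ok]), collapse = ", "))
  }
  out <- as.integer(grades >= grade_case_threshold(phenotype))
  attr(out, "n_missing") <- sum(is.na(grades))
  out
}

adjustment_terms <- function(phenotype) {
  switch(phenotype,
         neutropenia = c("trial", "age"),
         neuropathy = c("trial", "bmi", "pc1", "pc2"))
}

# Shared scaffolding for the logistic fits: assemble the complete-case model
# frame, run glm, and extract the Wald OR/CI/p for `term`.
fit_logistic_term <- function(dat, term, adjusted, phenotype, scale,
                              min_per_arm = 10) {
  covars <- if (adjusted) adjustment_terms(phenotype) else character(0)
  covars <- intersect(covars, names(dat))
  dat <- dat[stats::complete.cases(dat[c("case", term, covars)]), , drop = FALSE]
  n_case <- sum(dat$case == 1)
  n_ctrl <- sum(dat$case == 0)
  if (n_case < min_per_arm || n_ctrl < min_per_arm) {
    stop("too few cases (", n_case, ") or controls (", n_ctrl, ") for a fit")
  }
  if (stats::sd(dat[[term]]) == 0) stop("degenerate predictor: ", term)
  if ("trial" %in% covars) {
    # largest trial as reference; the choice does not affect score inference
    tab <- sort(table(dat$trial), decreasing = TRUE)
    dat$trial <- stats::relevel(factor(dat$trial), ref = names(tab)[1])
    if (nlevels(dat$trial) < 2) covars <- setdiff(covars, "trial")
  }
  fm <- stats::reformulate(c(term, covars), response = "case")
  fit <- stats::glm(fm, family = stats::binomial(), data = dat)
  if (!fit$converged) stop("logistic fit did not converge for ", term)
  co <- summary(fit)$coefficients
  b <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  if (se > 1e3) stop("separation suspected for ", term, " (SE ", round(se), ")")
  z <- stats::qnorm(0.975)
  res <- data.frame(term = term,
                    odds_ratio = exp(b),
                    ci_low = exp(b - z * se),
                    ci_high = exp(b + z * se),
                    p_value = co[term, "Pr(>|z|)"],
                    adjusted = adjusted, scale = scale,
                    n_used = nrow(dat),
                    stringsAsFactors = FALSE)
  class(res) <- c("association_result", "data.frame")
  res
}

#' Logistic association of a polygenic score with toxicity case status
#'
#' Fits a maximum-likelihood logistic regression of the dichotomized
#' phenotype on the score. The non-weighted score is reported per allele;
#' the weighted score is standardized on the analysis cohort and reported
#' per standard deviation. Adjusted fits use the pre-specified covariate
#' sets: trial and age for neutropenia; trial, BMI and the first two
#' principal components for neuropathy. Complete-case analysis; 95% Wald
#' confidence intervals and two-sided Wald p-values.
#'
#' @param cohort `data.frame` with `sample_id`, `<phenotype>_grade` and the
#'   adjustment covariates (`trial`, `age`, `bmi`, `pc1`, `pc2` as needed).
#' @param scores A `score_table` from [compute_scores()].
#' @param phenotype `"neutropenia"` or `"neuropathy"`.
#' @param score_kind `"unweighted"` (per-allele) or `"weighted"` (per-SD).
#' @param adjusted Whether to include the phenotype's covariate set.
#' @return One-row `association_result` data frame: `term`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `adjusted`, `scale`, `n_used`.
#' @export
fit_score_model <- function(cohort, scores,
                            phenotype = c("neutropenia", "neuropathy"),
                            score_kind = c("unweighted", "weighted"),
                            adjusted = FALSE) {
  phenotype <- match.arg(phenotype)
  score_kind <- match.arg(score_kind)
  dat <- merge(cohort, scores, by = "sample_id")
  dat$case <- dichotomize(dat[[paste0(phenotype, "_grade")]], phenotype)
  keep <- !is.na(dat$case)
  dat <- dat[keep, , drop = FALSE]
  if (score_kind == "weighted") {
    sd_w <- stats::sd(dat$weighted_score)
    if (sd_w == 0) stop("degenerate predictor: weighted score is constant")
    dat$score <- (dat$weighted_score - mean(dat$weighted_score)) / sd_w
    scale <- "per-SD"
    term_name <- "weighted_score_std"
  } else {
    dat$score <- dat$unweighted_score
    scale <- "per-allele"
    term_name <- "unweighted_score"
  }
  dat[[term_name]] <- dat$score
  fit_logistic_term(dat, term_name, adjusted, phenotype, scale)
}

#' Per-variant logistic scan
#'
#' Fits one logistic regression per variant (risk-allele dosage as the
#' predictor, same adjustment sets as [fit_score_model()]) and flags variants
#' significant at `alpha` (default 5e-4, roughly 0.05 / 94). Per-variant fit
#' failures (e.g. monomorphic variants) are recorded, not fatal. Results are
#' ordered by ascending p-value for downstream gene ranking.
#'
#' @param g Dosage matrix (samples x variants), rownames matching
#'   `cohort$sample_id`.
#' @param cohort As in [fit_score_model()].
#' @param phenotype `"neutropenia"` or `"neuropathy"`.
#' @param adjusted Whether to include the phenotype's covariate set.
#' @param alpha Significance threshold for the `significant` flag.
#' @return `association_result` data frame with one row per successfully
#'   fitted variant (`term` = rsid), a `significant` flag, ordered by
#'   ascending `p_value`; failed variants in attribute `failures` (named
#'   character vector of messages).
#' @export
per_variant_scan <- function(g, cohort,
                             phenotype = c("neutropenia", "neuropathy"),
                             adjusted = FALSE, alpha = 5e-4) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.matrix(g))
  base <- cohort
  base$case <- dichotomize(base[[paste0(phenotype, "_grade")]], phenotype)
  rows <- list()
  failures <- character(0)
  for (rs in colnames(g)) {
    dat <- base
    dat$dosage <- g[match(dat$sample_id, rownames(g)), rs]
    res <- tryCatch(fit_logistic_term(dat, "dosage", adjusted, phenotype,
                                      scale = "per-allele"),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[rs] <- res
    } else {
      res$term <- rs
      rows[[rs]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), odds_ratio = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0), adjusted = logical(0),
               scale = character(0), n_used = integer(0))
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p_value < alpha
  attr(out, "failures") <- failures
  attr(out, "alpha") <- alpha
  class(out) <- c("association_result", "data.frame")
  out
}

#' Proportional-hazards linkage of the risk score to relapse-free survival
#'
#' Cox regression of relapse-free survival on the non-weighted score
#' (per-allele hazard ratio), optionally adjusted for neutropenia
#' case-control status. The per-`k`-allele hazard ratio is the per-allele
#' hazard ratio raised to the power `k` (default 10).
#'
#' @param cohort `data.frame` with `rfs_time`, `rfs_event` and (when
#'   adjusting) `neutropenia_grade`.
#' @param scores A `score_table`.
#' @param adjust_for_neutropenia Include neutropenia case status (grade >= 3)
#'   as a covariate.
#' @param per_k_alleles Rescaling factor `k` for the reported per-k HR.
#' @return A `survival_result` list: `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value` (per allele), `hr_per_k`, `ci_low_per_k`, `ci_high_per_k`,
#'   `per_k_alleles`, `n_used`, `n_events`.
#' @export
fit_survival <- function(cohort, scores, adjust_for_neutropenia = FALSE,
                         per_k_alleles = 10L) {
  dat <- merge(cohort, scores, by = "sample_id")
  vars <- c("rfs_time", "rfs_event", "unweighted_score")
  covars <- character(0)
  if (adjust_for_neutropenia) {
    dat$neutropenia_case <- dichotomize(dat$neutropenia_grade, "neutropenia")
    covars <- "neutropenia_case"
  }
  dat <- dat[stats::complete.cases(dat[c(vars, covars)]), , drop = FALSE]
  if (sum(dat$rfs_event) < 10) {
    stop("fewer than 10 events; survival fit not attempted")
  }
  fm <- stats::reformulate(c("unweighted_score", covars),
                           response = "survival::Surv(rfs_time, rfs_event)")
  fit <- survival::coxph(fm, data = dat)
  co <- summary(fit)$coefficients
  b <- co["unweighted_score", "coef"]
  se <- co["unweighted_score", "se(coef)"]
  z <- stats::qnorm(0.975)
  k <- as.integer(per_k_alleles)
  structure(list(hazard_ratio = exp(b),
                 ci_low = exp(b - z * se), ci_high = exp(b + z * se),
                 p_value = co["unweighted_score", "Pr(>|z|)"],
                 hr_per_k = exp(k * b),
                 ci_low_per_k = exp(k * (b - z * se)),
                 ci_high_per_k = exp(k * (b + z * se)),
                 per_k_alleles = k,
                 adjusted_for_neutropenia = adjust_for_neutropenia,
                 n_used = nrow(dat), n_events = sum(dat$rfs_event)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("per-allele HR %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("per-%d-allele HR %.4f (95%% CI %.4f-%.4f)\n",
              x$per_k_alleles, x$hr_per_k, x$ci_low_per_k, x$ci_high_per_k))
  cat(sprintf("n = %d, events = %d%s\n", x$n_used, x$n_events,
              if (x$adjusted_for_neutropenia) ", adjusted for neutropenia"
              else ""))
  invisible(x)
}
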