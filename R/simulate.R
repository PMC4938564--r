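#' Simulation configuration for synthetic cohorts
#'
#' Collects the knobs of the synthetic-cohort generator. Defaults mirror the
#' cohort structure the analysis assumes: roughly 30% prevalence of
#' moderate-severe toxicity, a small protective per-allele effect of the
#' risk-allele count on toxicity (odds ratio 0.98), and a per-allele hazard
#' ratio of 1.02 for relapse-free survival.
#'
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed; all generators are deterministic given it.
#' @param theta_tox Per-allele log-odds of toxicity on the non-weighted score.
#' @param target_prevalence Marginal probability of being a toxicity case.
#' @param hr_per_allele Per-allele hazard ratio for relapse-free survival.
#' @param censor_rate Approximate fraction of samples censored.
#' @param use_imputation_noise Whether dosages get imputation noise matched to
#'   the catalog's per-variant r-squared.
#' @param baseline_hazard Baseline event hazard per year.
#' @param trial_levels,trial_probs Trial labels and multinomial mix.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples,
                              seed = 1L,
                              theta_tox = log(0.98),
                              target_prevalence = 0.30,
                              hr_per_allele = 1.02,
                              censor_rate = 0.30,
                              use_imputation_noise = TRUE,
                              baseline_hazard = 0.05,
                              trial_levels = c("NEAT", "tAnGo", "Neo-tAnGo",
                                               "nontrial"),
                              trial_probs = c(0.35, 0.30, 0.30, 0.05)) {
  stopifnot(n_samples >= 2, target_prevalence > 0, target_prevalence < 1,
            hr_per_allele > 0, censor_rate >= 0, censor_rate < 1,
            length(trial_levels) == length(trial_probs))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 theta_tox = theta_tox, target_prevalence = target_prevalence,
                 hr_per_allele = hr_per_allele, censor_rate = censor_rate,
                 use_imputation_noise = use_imputation_noise,
                 baseline_hazard = baseline_hazard,
                 trial_levels = trial_levels,
                 trial_probs = trial_probs / sum(trial_probs)),
            class = "simulation_config")
}

#' Simulate risk-allele dosages under Hardy-Weinberg equilibrium
#'
#' Draws hard genotypes G_ij ~ Binomial(2, p_j) independently across samples
#' and variants at the catalog's risk-allele frequencies, emulating a cohort
#' in Hardy-Weinberg equilibrium.
#'
#' @param catalog A `variant_catalog`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric matrix (samples x variants) with sample ids as rownames,
#'   rsids as colnames, and a logical attribute `is_imputed` marking variants
#'   with `imputation_r2 < 1`.
#' @export
simulate_genotypes <- function(catalog, n, seed = 1L) {
  stopifnot(inherits(catalog, "variant_catalog"), n >= 1)
  p <- catalog$risk_allele_freq
  g <- with_seed(seed, {
    m <- vapply(p, function(pj) stats::rbinom(n, 2L, pj), numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    m
  })
  dimnames(g) <- list(sprintf("S%05d", seq_len(n)), catalog$rsid)
  attr(g, "is_imputed") <- catalog$imputation_r2 < 1
  g
}

#' Add imputation uncertainty to hard genotype dosages
#'
#' Emulates imputed dosages with per-variant certainty r-squared: for a
#' variant with frequency p and info r2 < 1 the observed dosage is
#' `D = 2p + r2 (G - 2p) + e` with `e ~ Normal(0, r2 (1 - r2) 2p(1-p))`,
#' clipped to `[0, 2]`. Before clipping this gives `Var(D) = r2 * 2p(1-p)`
#' (the variance deflation imputation produces) and `cor(D, G) = r`.
#' Variants with r2 = 1 pass through unchanged.
#'
#' @param g Dosage matrix from [simulate_genotypes()].
#' @param catalog The matching `variant_catalog`.
#' @param seed Integer seed.
#' @param clip Clip dosages to `[0, 2]` (the default, matching real imputed
#'   dosages); `clip = FALSE` exposes the raw construction, whose variance
#'   ratio and correlation are exact, for diagnostics.
#' @return Dosage matrix of the same shape.
#' @export
apply_imputation_noise <- function(g, catalog, seed = 1L, clip = TRUE) {
  stopifnot(inherits(catalog, "variant_catalog"))
  idx <- match(colnames(g), catalog$rsid)
  if (anyNA(idx)) {
    stop("variants absent from catalog: ",
         paste(colnames(g)[is.na(idx)], collapse = ", "))
  }
  r2 <- catalog$imputation_r2[idx]
  p <- catalog$risk_allele_freq[idx]
  if (any(r2 <= 0 | r2 > 1)) stop("imputation_r2 outside (0, 1]")
  out <- with_seed(seed, {
    d <- g
    for (j in which(r2 < 1)) {
      vj <- 2 * p[j] * (1 - p[j])
      e <- stats::rnorm(nrow(g), 0, sqrt(r2[j] * (1 - r2[j]) * vj))
      d[, j] <- 2 * p[j] + r2[j] * (g[, j] - 2 * p[j]) + e
    }
    d
  })
  if (clip) out[] <- pmin(pmax(out, 0), 2)
  attr(out, "is_imputed") <- r2 < 1
  out
}

#' Simulate dichotomous toxicity and CTCAE grades from a score
#'
#' Case status is drawn binary-first from a logistic model
#' `logit P(case) = alpha + theta_tox * (score - mean(score))`, with the
#' intercept alpha calibrated by 1-D root finding so the expected marginal
#' case rate equals `target_prevalence` (tolerance 1e-6). Grades are then
#' sampled within the case and control strata in proportion to the packaged
#' grade-distribution counts, so a case can only receive a case-stratum grade
#' (neutropenia >= 3, neuropathy >= 2) and vice versa.
#'
#' @param scores Numeric vector of per-sample scores (the non-weighted score
#'   by convention), or a `ScoreTable` data frame from [compute_scores()].
#' @param cfg A `simulation_config` (supplies `theta_tox`,
#'   `target_prevalence`, `seed`).
#' @param phenotype `"neutropenia"` or `"neuropathy"`.
#' @param grade_table Grade-distribution table with columns `grade` and
#'   `<phenotype>_n`; defaults to the packaged distributions.
#' @return `data.frame` with `sample_id`, `case` (0/1) and `grade`.
#' @export
simulate_toxicity <- function(scores, cfg,
                              phenotype = c("neutropenia", "neuropathy"),
                              grade_table = default_grade_table()) {
  phenotype <- match.arg(phenotype)
  if (is.data.frame(scores)) {
    ids <- scores$sample_id
    s <- scores$unweighted_score
  } else {
    ids <- names(scores)
    s <- as.numeric(scores)
    if (is.null(ids)) ids <- sprintf("S%05d", seq_along(s))
  }
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$theta_tox != 0 && stats::sd(s) == 0) {
    stop("degenerate scores: zero variance with a nonzero toxicity effect")
  }
  eta <- cfg$theta_tox * (s - mean(s))
  alpha <- calibrate_intercept(eta, cfg$target_prevalence)
  counts <- grade_table[[paste0(phenotype, "_n")]]
  grades <- grade_table$grade
  thr <- grade_case_threshold(phenotype)
  case_gr <- grades >= thr
  with_seed(cfg$seed + 1L, {
    case <- stats::rbinom(length(s), 1L, stats::plogis(alpha + eta))
    grade <- integer(length(s))
    for (stratum in c(0L, 1L)) {
      pool <- if (stratum == 1L) case_gr else !case_gr
      pr <- counts[pool]
      if (sum(pr) <= 0) stop("grade table has no mass in the ",
                             if (stratum == 1L) "case" else "control",
                             " stratum")
      sel <- case == stratum
      grade[sel] <- sample(grades[pool], sum(sel), replace = TRUE,
                           prob = pr / sum(pr))
    }
    data.frame(sample_id = ids, case = case, grade = grade,
               stringsAsFactors = FALSE)
  })
}

# Solve the logistic intercept so that mean(plogis(alpha + eta)) hits the
# requested marginal prevalence; eta is already centred.
calibrate_intercept <- function(eta, prevalence, tol = 1e-6) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("target prevalence must lie strictly inside (0, 1)")
  }
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  stats::uniroot(f, interval = c(-35, 35), tol = tol)$root
}

grade_case_threshold <- function(phenotype) {
  switch(phenotype, neutropenia = 3L, neuropathy = 2L)
}

#' @rdname simulate_toxicity
#' @export
default_grade_table <- function() {
  utils::read.delim(system.file("extdata", "table2_grades.tsv",
                                package = "toxprs"),
                    comment.char = "#")
}

#' Simulate covariates and relapse-free survival
#'
#' Age ~ Normal(50, 8) truncated to [25, 75]; BMI ~ Normal(26, 4.5) truncated
#' to [16, 45]; trial assigned multinomially; pc1/pc2 ~ Normal(0, 1).
#' Relapse-free survival is exponential with hazard
#' `h0 * hr_per_allele^(score - mean(score))` and independent exponential
#' censoring whose rate is chosen to censor approximately `censor_rate` of
#' samples.
#'
#' @param n Number of samples (must match `length(scores)` when given).
#' @param cfg A `simulation_config`.
#' @param scores Numeric vector of non-weighted scores (or a score table).
#' @return `data.frame` with `sample_id`, `age`, `bmi`, `trial`, `pc1`,
#'   `pc2`, `rfs_time` (years), `rfs_event` (0/1).
#' @export
simulate_covariates_and_survival <- function(n, cfg, scores = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.data.frame(scores)) scores <- scores$unweighted_score
  if (is.null(scores)) scores <- rep(0, n)
  stopifnot(length(scores) == n)
  h0 <- cfg$baseline_hazard
  # With exponential event and censoring times, P(censored) = rc / (rc + h)
  # at the baseline hazard; solve for the censoring rate.
  rc <- if (cfg$censor_rate > 0) h0 * cfg$censor_rate / (1 - cfg$censor_rate)
        else 0
  with_seed(cfg$seed + 2L, {
    age <- rtruncnorm(n, 50, 8, 25, 75)
    bmi <- rtruncnorm(n, 26, 4.5, 16, 45)
    trial <- sample(cfg$trial_levels, n, replace = TRUE,
                    prob = cfg$trial_probs)
    pc1 <- stats::rnorm(n)
    pc2 <- stats::rnorm(n)
    hz <- h0 * cfg$hr_per_allele^(scores - mean(scores))
    t_event <- stats::rexp(n, hz)
    t_cens <- if (rc > 0) stats::rexp(n, rc) else rep(Inf, n)
    data.frame(sample_id = sprintf("S%05d", seq_len(n)),
               age = age, bmi = bmi, trial = trial, pc1 = pc1, pc2 = pc2,
               rfs_time = pmin(t_event, t_cens),
               rfs_event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

# Truncated normal via inverse-CDF sampling on the truncated quantile range.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running the full generator: Hardy-Weinberg genotypes,
#' optional imputation noise, polygenic scores, toxicity grades for both
#' phenotypes, covariates and survival.
#'
#' @param catalog A `variant_catalog`.
#' @param cfg A `simulation_config`.
#' @return List with elements `dosages`, `scores` (a score table) and
#'   `cohort` (covariates, `neutropenia_grade`, `neuropathy_grade`, survival).
#' @export
simulate_cohort <- function(catalog, cfg) {
  g <- simulate_genotypes(catalog, cfg$n_samples, cfg$seed)
  if (cfg$use_imputation_noise) {
    g <- apply_imputation_noise(g, catalog, cfg$seed + 10L)
  }
  scores <- compute_scores(g, catalog)
  neut <- simulate_toxicity(scores, cfg, "neutropenia")
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 20L
  neur <- simulate_toxicity(scores, cfg2, "neuropathy")
  cov <- simulate_covariates_and_survival(cfg$n_samples, cfg, scores)
  cohort <- cov
  cohort$neutropenia_grade <- neut$grade
  cohort$neuropathy_grade <- neur$grade
  list(dosages = g, scores = scores, cohort = cohort)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators compose deterministically.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
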