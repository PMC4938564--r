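---
title: "Methods: polygenic breast-cancer risk scores and chemotherapy toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic breast-cancer risk scores and chemotherapy toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxprs)
```

## The scientific question

Common breast-cancer susceptibility variants act through pathways — DNA
damage response above all — that are also the pathways by which cytotoxic
chemotherapy injures normal tissue. `toxprs` implements the analysis that
asks whether a patient's aggregate germline breast-cancer risk, summarised
as a polygenic risk score (PRS) over 94 confirmed susceptibility variants,
is associated with two clinically important chemotherapy toxicities:
chemotherapy-induced neutropenia and taxane-related sensory neuropathy. A
secondary analysis links the score to relapse-free survival.

## The polygenic scores

For patient $i$ with risk-allele dosages $G_{ij} \in [0, 2]$ over variants
$j = 1, \dots, 94$, two scores are computed:

$$\text{riskscore}_i = \sum_j G_{ij}, \qquad
  \text{weighted riskscore}_i = \sum_j \beta_j G_{ij},$$

where $\beta_j = \log \mathrm{OR}_j$ is the published per-allele log-odds
ratio for breast cancer. The catalog (`inst/extdata/table1_catalog.tsv`)
stores odds ratios exactly as published (2–3 decimals); weights are derived
at load time by `load_catalog()` so file and computation cannot diverge. The
catalog mixes two weight provenances (a mutually adjusted analysis for 77
variants, an unadjusted meta-analysis for 17 newer ones); the analysis
treats them uniformly, taking the printed values verbatim, since no
interaction adjustment for the newer variants has been published.

Association results are reported per allele for the non-weighted score and
per standard deviation for the weighted score; `standardize()` uses the
analysis cohort's sample SD (denominator $n-1$), because the per-SD
convention refers to the observed cohort, not to an analytic reference
population.

Missing dosages default to mean-imputation with the Hardy-Weinberg
expectation $2p_j$, which keeps cohort-level score moments unbiased;
`"skip"` and `"fail"` policies are available. Real cohorts with fully
imputed dosages never trigger this.

## Genotype quality control

`variant_qc()` applies the standard pre-imputation filters, each a *strict*
inequality so boundary values pass: variant missingness > 5%; MAF < 1%;
MAF < 5% together with missingness > 1%; exact Hardy-Weinberg
$p < 10^{-5}$. `sample_qc()` removes samples with > 10% of variants
missing. `qc_fixpoint()` iterates variant-then-sample filtering until
stable; that fixed iteration order is part of the contract (an arbitrary
starting order can rescue or doom borderline samples whose missingness is
concentrated in bad variants).

The Hardy-Weinberg test is the exact conditional test with the two-sided
probability-ordering convention: given the minor-allele count, the p-value
sums the probabilities of all heterozygote counts no more probable than the
observed one. The conditional distribution is built with a log-space ratio
recurrence, numerically exact for any sample size (the test suite checks
every configuration up to 200 samples against closed-form enumeration, to
1e-12). It operates on hard calls — dosages rounded to the nearest integer —
because the filter belongs upstream of imputation; in the simulated
pipeline, QC therefore precedes noise injection by default.

`compute_pcs()` furnishes the first principal components of the
column-standardized dosage matrix as population-structure covariates.
Zero-variance variants are dropped, missing entries mean-imputed, and each
component's sign is fixed by making its largest-magnitude loading positive,
so results are reproducible across BLAS implementations. Ancestry
*exclusion* is out of scope; the PCs exist to be adjusted for.

## Toxicity association

Toxicity grades (NCI CTCAE) are dichotomized by `dichotomize()`:
neutropenia cases are grade ≥ 3, neuropathy cases grade ≥ 2. Logistic
regressions (`fit_score_model()`) use maximum likelihood with Wald 95%
confidence intervals and two-sided Wald p-values — chosen to match the
symmetric interval style of the reported tables; the source analysis does
not state its interval method. Pre-specified adjustment sets are: trial and
age for neutropenia; trial, BMI and the first two principal components for
neuropathy. Trials enter as indicators with the largest trial as reference;
the reference choice cannot affect score inference. Analyses are complete
case, with `n_used` reported.

`per_variant_scan()` fits one model per variant with the same adjustment
sets and flags significance at $\alpha = 5 \times 10^{-4}$, stored as a
config default and interpretable as roughly $0.05 / 94$. Per-variant
failures (monomorphic variants, separation) are recorded, not fatal.

`fit_survival()` regresses relapse-free survival on the non-weighted score
with a Cox model, optionally adjusted for neutropenia case status, and
rescales the per-allele hazard ratio to a per-10-allele ratio as
$\mathrm{HR}^{10}$. Note that $1.02^{10} = 1.219$: a printed per-10 value
of 1.23 alongside a rounded per-allele 1.02 simply reflects exponentiation
of the unrounded coefficient.

## Ranked-gene pathway enrichment

The enrichment procedure mirrors the exploratory follow-up: map each
variant to a single gene, rank genes by the best (smallest) association
p-value among their variants regardless of effect direction
(`map_and_rank()`, ties broken by rsid), take the top 50% of the ranked
list with a floor convention (`top_fraction()`: 76 genes → 38), and test
each user-supplied GMT gene set for overrepresentation with a one-sided
hypergeometric upper-tail p-value (`fisher_overrepresentation()`),
Bonferroni-corrected over the sets actually tested.

Two deliberate departures from the original tooling: the test is a plain
Fisher exact test, not the EASE-penalized variant of the original
annotation web tool, and the background universe is the catalog's own
mapped gene list rather than an annotation database's genome background.
Consequently the originally printed enrichment p-values (0.004 / corrected
0.13 for p53 signalling) are not reproduction targets; the worked p53
example — three of the top 38 genes (*CCND1*, *CHEK2*, *MDM4*) in the set —
is. The packaged variant-to-gene mapping
(`variant_gene_map_synthetic.tsv`) is a best-effort reconstruction (the
published table resolves only the top 38 pairs) and is user-overridable.

## Statistical power

`analytic_power()` implements two-sample, two-sided normal-approximation
power for a difference $\Delta$ in mean score between cases and controls:

$$\mathrm{power} = \Phi(\lambda - z_{1-\alpha/2}) +
  \Phi(-\lambda - z_{1-\alpha/2}), \qquad
  \lambda = \frac{|\Delta|}{\sigma\sqrt{1/n_1 + 1/n_2}}.$$

The default $\sigma$ is the catalog-analytic weighted-score SD
$\sqrt{\sum_j \beta_j^2\, 2p_j(1-p_j)}$, which evaluates to 0.4568 on the
packaged 94-variant catalog. With $\Delta = 0.1$, 30% cases and
$\alpha = 0.05$ this gives 95% power at $n = 1279$ and 98% at $n = 1676$
(the originally stated 96%/99% are reproduced exactly if $\sigma$ is
computed over only the 77 mutually-adjusted variants, $\sigma = 0.435$;
which SD convention the original calculation used is not stated, so the
full-catalog SD is the package default and $\sigma$ is overridable). The
normal approximation rather than a noncentral *t* is deliberate: at group
sizes of ≈384/895 the difference is below half a percentage point.
`simulated_power()` cross-checks the formula by Monte Carlo with a
vectorized Welch t-test.

## The synthetic-cohort generator

No patient-level data are distributable, so `simulate_cohort()` generates
cohorts with exactly the structure the analysis assumes:

* **Genotypes** — $G_{ij} \sim \mathrm{Binomial}(2, p_j)$ independent
  across variants and samples at the catalog frequencies
  (Hardy-Weinberg equilibrium, linkage equilibrium).
* **Imputation noise** — for info $r^2 < 1$, the observed dosage is
  $D = 2p + r^2(G - 2p) + e$, $e \sim N(0,\, r^2(1-r^2)\,2p(1-p))$,
  clipped to $[0, 2]$. Pre-clip this yields exactly
  $\mathrm{Var}(D) = r^2 \cdot 2p(1-p)$ and $\mathrm{cor}(D, G) = r$ — the
  two properties of imputed dosages that matter downstream (variance
  deflation and dosage-truth correlation). The shrinkage-plus-jitter form
  is this package's model; only the per-variant info values themselves are
  taken from the catalog.
* **Toxicity** — binary-first: case status from
  $\mathrm{logit}\, P = \alpha + \theta\,(s_i - \bar s)$ with $\alpha$
  calibrated by 1-D root finding (tolerance $10^{-6}$) so the marginal
  prevalence equals the target (default 0.30); grades are then drawn
  within the case/control strata in proportion to the packaged grade
  distribution, so the grade marginals are matched in expectation and a
  case can never receive a control-stratum grade. $\theta$ is defined on
  the non-weighted score scale (default $\log 0.98$); any effect on the
  weighted score is induced, mirroring the observation that weighting
  attenuated the association.
* **Covariates** — age $\sim N(50, 8^2)$ truncated to $[25, 75]$ years,
  BMI $\sim N(26, 4.5^2)$ truncated to $[16, 45]$ kg/m², a four-trial
  multinomial mix (35/30/30/5%), PCs $\sim N(0, 1)$. These are plausible
  defaults for a UK adjuvant breast-cancer trial population, chosen once
  and config-overridable; the source reports its cohort characteristics
  only in supplementary material not reproduced here.
* **Survival** — exponential event times with hazard
  $h_0 \cdot \mathrm{HR}^{s_i - \bar s}$ ($h_0 = 0.05$/year, per-allele
  HR default 1.02) and independent exponential censoring with rate
  $h_0 c/(1-c)$, which censors a fraction $\approx c$ (default 0.30).

Everything is deterministic given the seed: generators run under a local
RNG state (`with_seed()`), derive per-stage seeds by fixed offsets, and
restore the caller's RNG.

What the generator does **not** emulate — linkage disequilibrium between
variants, genotyping batch effects, ancestry admixture, informative
censoring, correlation between the two toxicities within a patient, or
covariate-score confounding. Passing tests therefore demonstrate that the
estimators recover known truth under the stated sampling model, not that
the original cohort's estimates are correct.

## Numerical conventions and degenerate inputs

* Strict inequalities at every QC threshold; allele-count strata cuts
  (< 80, > 90) are strict, boundary values are `"mid"`.
* `top_fraction()` floors; rank ties break lexicographically by rsid.
* MAF folds the dosage mean at 0.5; all-missing variants fail QC with
  undefined MAF.
* Constant predictors, zero-variance scores, fewer than 10 cases, controls
  or events, unattainable prevalences, and suspected separation
  (Wald SE > 1000) are errors, not silent results.
* The Hardy-Weinberg p-value comparison uses a $1 + 10^{-9}$ relative
  tolerance when collecting "no more probable" outcomes, so floating-point
  ties are counted as ties.

## Problem sizes used in validation

The test suite validates moment identities at $n = 50{,}000$ simulated
samples, imputation-noise properties at $n = 100{,}000$ draws, parameter
recovery over 500 cohorts of $n = 1676$, Cox recovery at $n = 50{,}000$,
exact-test oracle equivalence over every Hardy-Weinberg configuration with
up to 200 samples and every 2×2 table with margins up to 100, and
Monte-Carlo power at 10,000 replicates. These sizes make Monte-Carlo error
small relative to the tolerances tested while keeping the default suite
fast to run.

## Known limitations

* The variant-to-gene mapping beyond the published top 38 pairs is a
  reconstruction; enrichment results on the full catalog depend on it.
* The generator's linkage-equilibrium assumption makes the analytic score
  variance exact; real catalogs with correlated variants (e.g. the three
  *TERT* or *CCND1* variants) would have a different score SD.
* Only dosage-format genotype input is supported (TSV or VCF `DS` field);
  no genotype calling, phasing or imputation.
* Build-37 positions as published; no liftover.
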