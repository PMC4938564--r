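#' Analytic power for a difference in mean risk score between toxicity groups
#'
#' Two-sample, two-sided normal-approximation power for detecting a
#' difference `mean_difference` in mean risk score between cases (fraction
#' `case_fraction` of `n_total`) and controls, with common score standard
#' deviation `score_sd`:
#' `power = Phi(ncp - z) + Phi(-ncp - z)` where
#' `ncp = |d| / (sd * sqrt(1/n1 + 1/n2))` and `z` is the upper `alpha/2`
#' normal quantile. With `mean_difference = 0` the power equals `alpha`.
#'
#' `score_sd` is typically the catalog-analytic weighted-score SD,
#' `sqrt(score_moments(catalog, weighted = TRUE)["variance"])`.
#'
#' @param n_total Total sample size.
#' @param case_fraction Fraction of cases in (0, 1); group sizes are
#'   `n1 = round(case_fraction * n_total)` and `n2 = n_total - n1`.
#' @param mean_difference Difference in mean score between groups.
#' @param score_sd Common score standard deviation (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
analytic_power <- function(n_total, case_fraction, mean_difference,
                           score_sd, alpha = 0.05) {
  stopifnot(case_fraction > 0, case_fraction < 1, alpha > 0, alpha < 1)
  if (score_sd <= 0) stop("score_sd must be positive")
  n1 <- round(case_fraction * n_total)
  n2 <- n_total - n1
  stopifnot(n1 >= 2, n2 >= 2)
  ncp <- abs(mean_difference) / (score_sd * sqrt(1 / n1 + 1 / n2))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Simulated power for the two-sample design
#'
#' Monte-Carlo cross-check of [analytic_power()]: draws case scores from
#' `Normal(mean_difference, score_sd^2)` and control scores from
#' `Normal(0, score_sd^2)` at the implied group sizes and rejects with a
#' two-sided Welch two-sample t-test at level `alpha`. The Welch statistic is
#' computed vectorized across replicates.
#'
#' @inheritParams analytic_power
#' @param replicates Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `power` (rejection fraction), `mc_se` (binomial
#'   standard error) and `replicates`.
#' @export
simulated_power <- function(n_total, case_fraction, mean_difference,
                            score_sd, alpha = 0.05, replicates = 10000,
                            seed = 1L) {
  stopifnot(replicates >= 100)
  if (score_sd <= 0) stop("score_sd must be positive")
  n1 <- round(case_fraction * n_total)
  n2 <- n_total - n1
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(replicates * n1, mean_difference, score_sd),
                 nrow = replicates)
    x2 <- matrix(stats::rnorm(replicates * n2, 0, score_sd),
                 nrow = replicates)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    reject <- 2 * stats::pt(-abs(tstat), df) < alpha
    power <- mean(reject)
    list(power = power,
         mc_se = sqrt(power * (1 - power) / replicates),
         replicates = replicates)
  })
}
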