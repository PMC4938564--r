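test_that("genotype simulation is deterministic and respects frequencies", {
  cat94 <- load_fixture_catalog()
  g1 <- simulate_genotypes(cat94, 50, seed = 11)
  g2 <- simulate_genotypes(cat94, 50, seed = 11)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genotypes(cat94, 50, seed = 12)))
  expect_true(all(g1 %in% 0:2))

  cat0 <- toy_catalog(p = 0)
  expect_true(all(simulate_genotypes(cat0, 100, seed = 1) == 0))
})

test_that("dosage moments match the binomial oracle at p = 0.5", {
  n <- 50000
  g <- simulate_genotypes(toy_catalog(p = 0.5), n, seed = 21)
  se_mean <- sqrt(0.5 / n)                  # sd of the mean of Binom(2, .5)
  expect_lt(abs(mean(g) - 1.0), 3 * se_mean)
  # variance of the sample variance of a binomial, normal-approx SE
  se_var <- sqrt(2 * 0.5^2 / n) * 2
  expect_lt(abs(var(as.numeric(g)) - 0.5), 3 * se_var)
})

test_that("simulated cohorts reproduce the analytic score moments", {
  cat94 <- load_fixture_catalog()
  n <- 50000
  g <- simulate_genotypes(cat94, n, seed = 31)
  sc <- compute_scores(g, cat94)
  mom <- score_moments(cat94, weighted = FALSE)
  se_mean <- sqrt(mom["variance"] / n)
  expect_lt(abs(mean(sc$unweighted_score) - mom["mean"]), 3 * se_mean)
  se_var <- sqrt(2 / (n - 1)) * mom["variance"]
  expect_lt(abs(var(sc$unweighted_score) - mom["variance"]), 3 * se_var)
  momw <- score_moments(cat94, weighted = TRUE)
  expect_lt(abs(mean(sc$weighted_score) - momw["mean"]),
            3 * sqrt(momw["variance"] / n))
})

test_that("simulated genotypes pass the Hardy-Weinberg screen", {
  cat94 <- load_fixture_catalog()
  g <- simulate_genotypes(cat94, 2000, seed = 41)
  hc <- hard_call_counts(g)
  p <- mapply(hwe_exact_test, hc$n0, hc$n1, hc$n2)
  expect_equal(sum(p < 1e-5), 0)
})

test_that("imputation noise reproduces the target r-squared", {
  r2 <- 0.81  # certainty of the least well imputed common variant class
  catA <- toy_catalog(p = 0.43, r2 = r2)
  g <- simulate_genotypes(catA, 100000, seed = 51)
  d <- apply_imputation_noise(g, catA, seed = 52)
  expect_lt(abs(cor(as.numeric(d), as.numeric(g))^2 - r2), 0.02)

  r2 <- 0.52  # heavily uncertain imputation
  catB <- toy_catalog(p = 0.34, r2 = r2)
  g <- simulate_genotypes(catB, 100000, seed = 53)
  # variance deflation is exact before clipping to [0, 2]
  d_raw <- apply_imputation_noise(g, catB, seed = 54, clip = FALSE)
  p <- 0.34
  expect_lt(abs(var(as.numeric(d_raw)) / (2 * p * (1 - p)) - r2), 0.03)
  d <- apply_imputation_noise(g, catB, seed = 54)
  expect_equal(cor(as.numeric(d), as.numeric(d_raw)), 1, tolerance = 0.05)

  catC <- toy_catalog(p = 0.3, r2 = 1)
  g <- simulate_genotypes(catC, 1000, seed = 55)
  expect_equal(apply_imputation_noise(g, catC, seed = 56)[, 1],
               g[, 1])
  expect_true(all(d >= 0 & d <= 2))
})

test_that("toxicity simulation hits the target prevalence under the null", {
  n <- 50000
  cfg <- simulation_config(n, seed = 61, theta_tox = 0,
                           target_prevalence = 0.30)
  s <- rnorm(n, 87, 5.9)
  tox <- simulate_toxicity(s, cfg, "neutropenia")
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(tox$case) - 0.30), 3 * se)
})

test_that("grades are sampled within strata in the printed proportions", {
  n <- 60000
  cfg <- simulation_config(n, seed = 62, theta_tox = 0)
  tox_nt <- simulate_toxicity(rnorm(n, 87, 5.9), cfg, "neutropenia")
  # conservation: cases only get case-stratum grades and vice versa
  expect_true(all(tox_nt$grade[tox_nt$case == 1] >= 3))
  expect_true(all(tox_nt$grade[tox_nt$case == 0] <= 2))
  ctrl <- table(factor(tox_nt$grade[tox_nt$case == 0], levels = 0:2))
  expect_equal(as.numeric(ctrl / sum(ctrl)),
               c(733, 199, 245) / (733 + 199 + 245), tolerance = 0.05)

  tox_np <- simulate_toxicity(rnorm(n, 87, 5.9), cfg, "neuropathy")
  expect_true(all(tox_np$grade[tox_np$case == 1] %in% 2:3))
  case <- table(factor(tox_np$grade[tox_np$case == 1], levels = 2:3))
  expect_equal(as.numeric(case / sum(case)), c(304, 56) / 360,
               tolerance = 0.05)
})

test_that("toxicity simulation rejects degenerate inputs", {
  cfg <- simulation_config(100, seed = 63)
  expect_error(simulate_toxicity(rep(1, 100), cfg, "neutropenia"),
               "degenerate")
  expect_error(simulation_config(100, target_prevalence = 0))
})

test_that("covariates and survival have the configured structure", {
  n <- 20000
  cfg <- simulation_config(n, seed = 71, hr_per_allele = 1.0,
                           censor_rate = 0.3)
  cohort <- simulate_covariates_and_survival(n, cfg, rnorm(n, 87, 5.9))
  expect_true(all(cohort$age >= 25 & cohort$age <= 75))
  expect_true(all(cohort$bmi >= 16 & cohort$bmi <= 45))
  expect_true(all(cohort$rfs_time > 0))
  expect_setequal(unique(cohort$trial), cfg$trial_levels)
  expect_lt(abs(mean(cohort$rfs_event) - 0.7), 0.02)

  # all-censoring limit: censor_rate near 1 makes events vanishingly rare
  cfg2 <- simulation_config(500, seed = 72, censor_rate = 0.999)
  c2 <- simulate_covariates_and_survival(500, cfg2, rnorm(500))
  expect_lt(mean(c2$rfs_event), 0.02)
})

test_that("survival generator recovers a null and a 1.02 per-allele hazard", {
  cat94 <- load_fixture_catalog()
  n <- 50000
  cfg <- simulation_config(n, seed = 81, hr_per_allele = 1.02)
  g <- simulate_genotypes(cat94, n, seed = 82)
  sc <- compute_scores(g, cat94)
  cohort <- simulate_covariates_and_survival(n, cfg, sc)
  fit <- fit_survival(cohort, sc)
  expect_true(fit$ci_low <= 1.02 && 1.02 <= fit$ci_high)
  expect_equal(fit$hazard_ratio, 1.02, tolerance = 0.01)
})

test_that("the whole generator is reproducible given a seed", {
  cat94 <- load_fixture_catalog()
  cfg <- simulation_config(200, seed = 91)
  s1 <- simulate_cohort(cat94, cfg)
  s2 <- simulate_cohort(cat94, cfg)
  expect_identical(s1, s2)
})
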