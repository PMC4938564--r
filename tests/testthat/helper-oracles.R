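# Shared fixtures and independent oracles used across the suite.

catalog_path <- function() {
  system.file("extdata", "table1_catalog.tsv", package = "toxprs")
}

load_fixture_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_catalog(catalog_path())
    cache
  }
})

table4_fixture <- function() {
  read.delim(system.file("extdata", "table4_ranked_genes.tsv",
                         package = "toxprs"), comment.char = "#")
}

grades_fixture <- function() {
  read.delim(system.file("extdata", "table2_grades.tsv", package = "toxprs"),
             comment.char = "#")
}

# Build a minimal in-memory catalog for constructed scenarios.
toy_catalog <- function(p, or = rep(1.1, length(p)), r2 = rep(1, length(p)),
                        rsid = sprintf("rsT%03d", seq_along(p))) {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(rsid = rsid, gene = paste0("G", seq_along(p)),
                         chr = "1", position = seq_along(p),
                         risk_allele = "A", odds_ratio = or,
                         risk_allele_freq = p, imputation_r2 = r2),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_catalog(path)
}

# Exact conditional heterozygote distribution oracle: enumerate all genotype
# configurations compatible with the allele-count margins and weight them by
# the Hardy-Weinberg multinomial probability (any allele frequency gives the
# same conditional law; 0.5 is used). Independent of the package's ratio
# recurrence.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * min(n0, n2) + n1
  hs <- seq.int(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hs, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    dmultinom(c(bb, h, aa), prob = c(0.25, 0.5, 0.25))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[match(n1, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Hypergeometric upper-tail oracle by direct density summation.
fisher_oracle <- function(k, list_size, set_size, background) {
  ks <- k:min(list_size, set_size)
  sum(dhyper(ks, set_size, background - set_size, list_size))
}

# Deterministic small cohort (scores + grades + covariates) for fit tests.
make_test_cohort <- function(n = 1500, seed = 101, theta = log(0.9),
                             phenotype = "neutropenia") {
  cat94 <- load_fixture_catalog()
  cfg <- simulation_config(n, seed = seed, theta_tox = theta)
  g <- simulate_genotypes(cat94, n, seed)
  scores <- compute_scores(g, cat94)
  tox <- simulate_toxicity(scores, cfg, phenotype)
  cohort <- simulate_covariates_and_survival(n, cfg, scores)
  cohort[[paste0(phenotype, "_grade")]] <- tox$grade
  list(dosages = g, scores = scores, cohort = cohort, cfg = cfg,
       catalog = cat94)
}
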