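test_that("Hardy-Weinberg exact test matches the enumeration oracle", {
  expect_identical(hwe_exact_test(100, 0, 0), 1)
  p_deficit <- hwe_exact_test(57, 14, 50)
  expect_equal(p_deficit, hwe_oracle(57, 14, 50), tolerance = 1e-12)
  expect_lt(p_deficit, 1e-5)
  p_mode <- hwe_exact_test(25, 50, 25)
  expect_equal(p_mode, hwe_oracle(25, 50, 25), tolerance = 1e-12)
  expect_gt(p_mode, 0.9)
  # random configurations across sample sizes
  set.seed(7)
  for (i in 1:60) {
    n <- sample(1:150, 1)
    n1 <- sample(0:n, 1)
    n2 <- sample(0:(n - n1), 1)
    n0 <- n - n1 - n2
    expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
})

test_that("variant filters follow the four rules with strict inequalities", {
  # columns constructed to hit each rule; n = 1000 samples
  n <- 1000
  set.seed(5)
  mk <- function(p, n_miss = 0) {
    v <- rbinom(n, 2, p)
    if (n_miss > 0) v[seq_len(n_miss)] <- NA
    v
  }
  g <- cbind(rare = mk(0.008),           # MAF < 1%
             lowmaf_miss = mk(0.03, 20), # MAF < 5% & missing 2% > 1%
             high_miss = mk(0.3, 60),    # missing 6% > 5%
             clean = mk(0.2, 40))        # MAF 20%, missing 4%: passes
  hwe_bad <- c(rep(0, 470), rep(2, 430), rep(1, 100))  # het deficit
  g <- cbind(g, hwe_bad = hwe_bad)
  rep_ <- variant_qc(g)
  v <- rep_$variants
  expect_false(v$pass[v$rsid == "rare"])
  expect_match(v$reasons[v$rsid == "rare"], "MAF<1%")
  expect_false(v$pass[v$rsid == "lowmaf_miss"])
  expect_match(v$reasons[v$rsid == "lowmaf_miss"], "MAF<5% & missing>1%")
  expect_false(v$pass[v$rsid == "high_miss"])
  expect_match(v$reasons[v$rsid == "high_miss"], "missing>5%")
  expect_true(v$pass[v$rsid == "clean"])
  expect_false(v$pass[v$rsid == "hwe_bad"])
  expect_match(v$reasons[v$rsid == "hwe_bad"], "HWE")
  expect_setequal(rep_$retained, "clean")
  # failure reasons exist iff the variant fails
  expect_identical(v$pass, v$reasons == "")
})

test_that("boundary values pass under strict-inequality semantics", {
  n <- 1000
  set.seed(6)
  exact_miss <- function(p, frac) {
    v <- rbinom(n, 2, p)
    v[seq_len(n * frac)] <- NA
    v
  }
  g <- cbind(m5 = exact_miss(0.3, 0.05),    # missing exactly 5%
             maf1 = c(rep(1, 20), rep(0, 980)),  # MAF exactly 1%
             lowmaf_m1 = exact_miss(0.03, 0.01)) # MAF<5%, missing exactly 1%
  v <- variant_qc(g)$variants
  expect_true(v$pass[v$rsid == "m5"])
  expect_true(v$pass[v$rsid == "maf1"])
  expect_true(v$pass[v$rsid == "lowmaf_m1"])
})

test_that("all-missing variants fail with undefined MAF", {
  g <- cbind(dead = rep(NA_real_, 50), live = rbinom(50, 2, 0.4))
  v <- variant_qc(g)$variants
  expect_false(v$pass[v$rsid == "dead"])
  expect_true(is.na(v$maf[v$rsid == "dead"]))
  expect_match(v$reasons[v$rsid == "dead"], "missing")
})

test_that("sample filter removes >10% missingness, boundary retained", {
  g <- matrix(rbinom(40 * 200, 2, 0.3), nrow = 40,
              dimnames = list(sprintf("P%02d", 1:40),
                              sprintf("rs%03d", 1:200)))
  g[1, 1:24] <- NA   # 12% missing: removed
  g[2, 1:20] <- NA   # exactly 10%: retained
  rep_ <- sample_qc(g)
  expect_false("P01" %in% rep_$retained)
  expect_true("P02" %in% rep_$retained)
  expect_true(all(sprintf("P%02d", 3:40) %in% rep_$retained))
})

test_that("filter composition reaches an order-independent fixpoint", {
  set.seed(8)
  g <- matrix(rbinom(60 * 30, 2, 0.3), nrow = 60,
              dimnames = list(sprintf("P%02d", 1:60),
                              sprintf("rs%03d", 1:30)))
  g[1:4, 1:10] <- NA           # missingness concentrated in a corner
  g[5, ] <- NA                 # hopeless sample
  g[, 11] <- c(rep(0, 30), rep(2, 30))  # gross HWE failure
  fp <- qc_fixpoint(g)
  # re-running either filter on the fixpoint removes nothing further
  expect_identical(variant_qc(fp$dosages)$retained, colnames(fp$dosages))
  expect_identical(sample_qc(fp$dosages)$retained, rownames(fp$dosages))
  # iterating again from the fixpoint is the identity: the final set is
  # a genuine fixpoint of the variant-then-sample iteration
  fp2 <- qc_fixpoint(fp$dosages)
  expect_identical(fp2$variants_retained, fp$variants_retained)
  expect_identical(fp2$samples_retained, fp$samples_retained)
  # and the iteration is deterministic: same input, same final set
  fp3 <- qc_fixpoint(g)
  expect_identical(fp3$variants_retained, fp$variants_retained)
  expect_identical(fp3$samples_retained, fp$samples_retained)
})

test_that("principal components are orthogonal and ignore constant variants", {
  set.seed(9)
  g <- matrix(rbinom(100 * 40, 2, 0.4), nrow = 100,
              dimnames = list(sprintf("P%03d", 1:100),
                              sprintf("rs%03d", 1:40)))
  g_const <- cbind(g, constvar = rep(1, 100))
  p1 <- compute_pcs(g, 4)
  p2 <- compute_pcs(g_const, 4)
  expect_equal(p1, p2)
  cross <- crossprod(p1)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)
})

test_that("PC1 separates two simulated subpopulations", {
  set.seed(10)
  n_per <- 80; m <- 60
  p_a <- runif(m, 0.2, 0.5)
  p_b <- pmin(p_a + 0.25, 0.95)  # systematic allele-frequency offset
  ga <- sapply(p_a, function(p) rbinom(n_per, 2, p))
  gb <- sapply(p_b, function(p) rbinom(n_per, 2, p))
  g <- rbind(ga, gb)
  dimnames(g) <- list(sprintf("P%03d", 1:(2 * n_per)),
                      sprintf("rs%03d", 1:m))
  pcs <- compute_pcs(g, 2)
  pop <- rep(c("a", "b"), each = n_per)
  expect_lt(t.test(pcs[pop == "a", 1], pcs[pop == "b", 1])$p.value, 1e-10)
})

test_that("requesting more components than the rank warns and truncates", {
  g <- matrix(rbinom(3 * 5, 2, 0.5), nrow = 3,
              dimnames = list(paste0("P", 1:3), paste0("rs", 1:5)))
  expect_warning(pcs <- compute_pcs(g, 5), "rank")
  expect_lte(ncol(pcs), 3)
})
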