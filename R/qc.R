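#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test with the probability-ordering convention:
#' given the minor-allele count and sample size, the p-value is the total
#' probability of all heterozygote counts whose conditional probability under
#' Hardy-Weinberg equilibrium does not exceed that of the observed count.
#' The conditional distribution of the heterozygote count is computed by a
#' numerically stable ratio recurrence, so the test is exact for any sample
#' size. Always returns a value in (0, 1].
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts (the test is
#'   symmetric in the two homozygote labels).
#' @return Exact p-value.
#' @export
#' @examples
#' hwe_exact_test(57, 14, 50)   # gross heterozygote deficit, tiny p
#' hwe_exact_test(25, 50, 25)   # counts at the conditional mode, p near 1
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  if (n_hom_major < 0 || n_het < 0 || n_hom_minor < 0) {
    stop("genotype counts must be non-negative")
  }
  n <- n_hom_major + n_het + n_hom_minor
  if (n < 1) stop("at least one genotyped sample required")
  n_a <- 2 * min(n_hom_major, n_hom_minor) + n_het  # minor-allele count
  probs <- hwe_het_distribution(n, n_a)
  obs <- as.character(n_het)
  if (is.na(probs[obs])) stop("heterozygote count incompatible with margins")
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-9)])
  min(p, 1)
}

# Conditional distribution of the heterozygote count given n samples and
# minor-allele count n_a, named by heterozygote count. Feasible counts share
# the parity of n_a. Built in log space with the cumulated probability ratio
# P(h+2)/P(h) = (n_a - h)(2n - n_a - h) / ((h + 2)(h + 1)), then normalized;
# working with log ratios keeps the recurrence stable for any sample size.
hwe_het_distribution <- function(n, n_a) {
  n_b <- 2 * n - n_a
  h_vals <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  k <- length(h_vals)
  lp <- if (k == 1) 0 else {
    h <- h_vals[-k]
    c(0, cumsum(log(n_a - h) + log(n_b - h) - log(h + 2) - log(h + 1)))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  names(pr) <- h_vals
  pr
}

#' Derive hard genotype calls and counts from a dosage matrix
#'
#' Rounds dosages to the nearest integer genotype and tabulates, per variant,
#' the genotype counts needed by the Hardy-Weinberg test. Missing entries are
#' ignored.
#'
#' @param g Dosage matrix (samples x variants), values in `[0, 2]` or `NA`.
#' @return `data.frame` with one row per variant: `rsid`, `n0`, `n1`, `n2`
#'   (counts of rounded dosage 0/1/2).
#' @export
hard_call_counts <- function(g) {
  hc <- round(g)
  cnt <- function(v, k) sum(v == k, na.rm = TRUE)
  data.frame(rsid = colnames(g),
             n0 = apply(hc, 2, cnt, 0),
             n1 = apply(hc, 2, cnt, 1),
             n2 = apply(hc, 2, cnt, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variant-level quality control
#'
#' Applies the standard pre-imputation variant filters. A variant fails iff
#' at least one of:
#' * missing fraction > `max_missing` (default 5%),
#' * MAF < `min_maf` (default 1%),
#' * MAF < `lowmaf` (5%) and missing fraction > `lowmaf_max_missing` (1%),
#' * exact Hardy-Weinberg p-value < `hwe_p_min` (1e-5).
#'
#' All thresholds are strict inequalities, so boundary values pass. MAF is
#' computed from non-missing dosages as `min(m/2, 1 - m/2)` with `m` the mean
#' dosage; the Hardy-Weinberg test runs on hard calls (rounded dosages).
#' An all-missing variant fails the missingness rule with undefined MAF.
#'
#' @param g Dosage matrix (samples x variants).
#' @param max_missing,min_maf,lowmaf,lowmaf_max_missing,hwe_p_min Thresholds.
#' @return A `qc_report` list with `variants` (per-variant metrics, `pass`
#'   flag and semicolon-joined `reasons`) and `retained` (passing rsids).
#' @export
variant_qc <- function(g, max_missing = 0.05, min_maf = 0.01,
                       lowmaf = 0.05, lowmaf_max_missing = 0.01,
                       hwe_p_min = 1e-5) {
  stopifnot(is.matrix(g), ncol(g) >= 1)
  miss <- colMeans(is.na(g))
  m <- colMeans(g, na.rm = TRUE)
  maf <- pmin(m / 2, 1 - m / 2)
  maf[miss == 1] <- NA_real_
  hc <- hard_call_counts(g)
  hwe_p <- rep(NA_real_, ncol(g))
  ok <- hc$n0 + hc$n1 + hc$n2 > 0
  hwe_p[ok] <- mapply(hwe_exact_test, hc$n0[ok], hc$n1[ok], hc$n2[ok])
  reasons <- vector("list", ncol(g))
  for (j in seq_len(ncol(g))) {
    r <- character(0)
    if (miss[j] > max_missing || miss[j] == 1) r <- c(r, "missing>5%")
    if (!is.na(maf[j]) && maf[j] < min_maf) r <- c(r, "MAF<1%")
    if (!is.na(maf[j]) && maf[j] < lowmaf && miss[j] > lowmaf_max_missing) {
      r <- c(r, "MAF<5% & missing>1%")
    }
    if (!is.na(hwe_p[j]) && hwe_p[j] < hwe_p_min) r <- c(r, "HWE p<1e-5")
    reasons[[j]] <- r
  }
  pass <- lengths(reasons) == 0
  variants <- data.frame(rsid = colnames(g), missing_fraction = miss,
                         maf = maf, hwe_p = hwe_p, pass = pass,
                         reasons = vapply(reasons, paste, "", collapse = ";"),
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(variants = variants, retained = colnames(g)[pass]),
            class = "qc_report")
}

#' Sample-level quality control
#'
#' A sample fails iff its fraction of missing variant calls exceeds
#' `max_missing` (default 10%, strict inequality: exactly 10% passes).
#'
#' @param g Dosage matrix (samples x variants).
#' @param max_missing Missingness threshold.
#' @return A `qc_report` list with `samples` (per-sample metrics) and
#'   `retained` (passing sample ids).
#' @export
sample_qc <- function(g, max_missing = 0.10) {
  stopifnot(is.matrix(g), nrow(g) >= 1)
  miss <- rowMeans(is.na(g))
  pass <- miss <= max_missing  # fails only when strictly greater
  samples <- data.frame(sample_id = rownames(g), missing_fraction = miss,
                        pass = pass, row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(samples = samples, retained = rownames(g)[pass]),
            class = "qc_report")
}

#' Iterate variant and sample filters to a fixpoint
#'
#' Alternates [variant_qc()] and [sample_qc()] on the retained submatrix
#' until neither removes anything, yielding a final set that does not depend
#' on which filter ran first.
#'
#' @param g Dosage matrix.
#' @param ... Thresholds passed to [variant_qc()].
#' @param sample_max_missing Threshold passed to [sample_qc()].
#' @return List with `dosages` (filtered matrix), `variants_retained`,
#'   `samples_retained`, and the last per-variant/per-sample reports.
#' @export
qc_fixpoint <- function(g, ..., sample_max_missing = 0.10) {
  repeat {
    vq <- variant_qc(g, ...)
    g2 <- g[, vq$retained, drop = FALSE]
    sq <- sample_qc(g2, max_missing = sample_max_missing)
    g3 <- g2[sq$retained, , drop = FALSE]
    if (identical(dim(g3), dim(g))) {
      return(list(dosages = g3, variants_retained = colnames(g3),
                  samples_retained = rownames(g3),
                  variant_report = vq, sample_report = sq))
    }
    g <- g3
  }
}

#' Principal components of the dosage matrix
#'
#' Computes sample principal components of the column-standardized dosage
#' matrix (each variant centred and scaled to unit variance; zero-variance
#' variants dropped; missing entries mean-imputed before standardization).
#' The sign of each component is fixed by making its largest-magnitude
#' variant loading positive, so results are reproducible across platforms.
#'
#' @param g Dosage matrix (samples x variants).
#' @param k Number of components requested.
#' @return Matrix (samples x k) of PC coordinates, columns `PC1`, `PC2`, ...;
#'   if `k` exceeds the rank, the available components are returned with a
#'   warning.
#' @export
compute_pcs <- function(g, k = 2) {
  stopifnot(is.matrix(g), nrow(g) >= 2, k >= 1)
  x <- g
  for (j in seq_len(ncol(x))) {
    mj <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mj
  }
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) stop("fewer than 2 variable variants for PCA")
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  avail <- sum(pc$sdev > 1e-12)
  if (k > avail) {
    warning("requested ", k, " components but rank is ", avail,
            "; returning ", avail)
    k <- avail
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    load <- pc$rotation[, i]
    if (load[which.max(abs(load))] < 0) scores[, i] <- -scores[, i]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(g)
  scores
}
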