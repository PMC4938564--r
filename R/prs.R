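#' Compute non-weighted and weighted polygenic risk scores
#'
#' The non-weighted score is the sum of a patient's risk-allele dosages over
#' the catalog variants; the weighted score multiplies each dosage by the
#' variant's per-allele log-odds ratio for breast cancer,
#' `beta_j = log(odds_ratio_j)`.
#'
#' Missing dosages are handled per `missing_policy`:
#' * `"mean_impute"` (default): substitute the Hardy-Weinberg expectation
#'   `2 p_j`, which leaves cohort-level score moments unbiased;
#' * `"skip"`: missing entries contribute 0;
#' * `"fail"`: any missing dosage is an error.
#'
#' @param g Dosage matrix (samples x variants); every column must be present
#'   in the catalog, dosages in `[0, 2]`, oriented to the catalog risk
#'   allele.
#' @param catalog A `variant_catalog`.
#' @param missing_policy One of `"mean_impute"`, `"skip"`, `"fail"`.
#' @return A `score_table` data frame: `sample_id`, `unweighted_score`,
#'   `weighted_score`.
#' @export
compute_scores <- function(g, catalog,
                           missing_policy = c("mean_impute", "skip", "fail")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(g), inherits(catalog, "variant_catalog"))
  idx <- match(colnames(g), catalog$rsid)
  if (anyNA(idx)) {
    stop("variants absent from catalog: ",
         paste(colnames(g)[is.na(idx)], collapse = ", "))
  }
  rng <- range(g, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2]")
  if (anyNA(g)) {
    if (missing_policy == "fail") stop("missing dosages with policy 'fail'")
    fill <- if (missing_policy == "mean_impute") {
      2 * catalog$risk_allele_freq[idx]
    } else rep(0, length(idx))
    for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- fill[j]
  }
  beta <- catalog$weight[idx]
  out <- data.frame(sample_id = rownames(g),
                    unweighted_score = as.numeric(g %*% rep(1, ncol(g))),
                    weighted_score = as.numeric(g %*% beta),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Standardize the weighted score to zero mean and unit variance
#'
#' Adds `weighted_score_std = (weighted_score - mean) / sd`, with the sample
#' standard deviation (denominator n - 1) of the scored cohort, matching the
#' per-standard-deviation odds-ratio convention for weighted scores.
#'
#' @param scores A `score_table` from [compute_scores()].
#' @return The table with a `weighted_score_std` column added.
#' @export
standardize <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 2)
  s <- stats::sd(scores$weighted_score)
  if (s == 0) stop("degenerate input: weighted score has zero variance")
  scores$weighted_score_std <-
    (scores$weighted_score - mean(scores$weighted_score)) / s
  scores
}

#' Stratify patients by risk-allele count
#'
#' Labels patients `"low"` when the non-weighted score is strictly below
#' `low_cut`, `"high"` when strictly above `high_cut`, and `"mid"` otherwise
#' (boundary values are `"mid"`). The defaults reproduce the comparison of
#' patients carrying more than 90 risk alleles with those carrying fewer
#' than 80.
#'
#' @param scores A `score_table` or numeric vector of non-weighted scores.
#' @param low_cut,high_cut Cut points, `low_cut < high_cut`.
#' @return Character vector of labels in `{"low", "mid", "high"}`.
#' @export
allele_count_strata <- function(scores, low_cut = 80, high_cut = 90) {
  stopifnot(low_cut < high_cut)
  s <- if (is.data.frame(scores)) scores$unweighted_score else scores
  ifelse(s < low_cut, "low", ifelse(s > high_cut, "high", "mid"))
}
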