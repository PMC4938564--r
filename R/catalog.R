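#' Load a breast-cancer risk-variant catalog
#'
#' Reads a tab-separated catalog of risk variants (one row per variant) and
#' validates it. The per-allele log-odds weight `weight = log(odds_ratio)` is
#' derived at load time and never stored in the file, so the fixture and the
#' computation cannot drift.
#'
#' The packaged catalog of 94 confirmed breast-cancer susceptibility variants
#' ships at `system.file("extdata", "table1_catalog.tsv", package = "toxprs")`.
#'
#' @param path Path to a UTF-8 TSV file with header columns `rsid`, `gene`,
#'   `chr`, `position`, `risk_allele`, `odds_ratio`, `risk_allele_freq`,
#'   `imputation_r2`. Lines starting with `#` are ignored.
#' @param source_note Free-text provenance note attached to the catalog.
#'
#' @return A `variant_catalog`: a `data.frame` with the file's columns plus
#'   `weight`, row order preserved, and attribute `source_note`.
#' @export
#' @examples
#' cat94 <- load_catalog(system.file("extdata", "table1_catalog.tsv",
#'                                   package = "toxprs"))
#' nrow(cat94)  # 94
load_catalog <- function(path, source_note = paste("loaded from", path)) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("rsid", "gene", "chr", "position", "risk_allele",
                "odds_ratio", "risk_allele_freq", "imputation_r2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[required]
  num_cols <- c("position", "odds_ratio", "risk_allele_freq", "imputation_r2")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]) & nzchar(x[[col]]))
    if (any(is.na(v))) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("non-numeric or missing '", col, "' in catalog row ", row,
           " (rsid ", x$rsid[row], ")")
    }
    x[[col]] <- v
  }
  validate_catalog_fields(x)
  x$weight <- log(x$odds_ratio)
  attr(x, "source_note") <- source_note
  class(x) <- c("variant_catalog", "data.frame")
  x
}

validate_catalog_fields <- function(x) {
  dup <- duplicated(x$rsid)
  if (any(dup)) {
    stop("duplicate rsid in catalog row ", which(dup)[1],
         " (rsid ", x$rsid[which(dup)[1]], ")")
  }
  bad <- which(x$risk_allele_freq < 0 | x$risk_allele_freq > 1)
  if (length(bad)) {
    stop("risk_allele_freq outside [0, 1] in catalog row ", bad[1],
         " (rsid ", x$rsid[bad[1]], ")")
  }
  bad <- which(x$odds_ratio <= 0)
  if (length(bad)) {
    stop("odds_ratio must be positive in catalog row ", bad[1],
         " (rsid ", x$rsid[bad[1]], ")")
  }
  bad <- which(x$imputation_r2 <= 0 | x$imputation_r2 > 1)
  if (length(bad)) {
    stop("imputation_r2 outside (0, 1] in catalog row ", bad[1],
         " (rsid ", x$rsid[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Write a variant catalog back to TSV
#'
#' Inverse of [load_catalog()]: writes the stored columns (the derived
#' `weight` column is dropped) so that a write/load round trip preserves the
#' catalog.
#'
#' @param catalog A `variant_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "variant_catalog"))
  out <- as.data.frame(catalog)
  out$weight <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analytic moments of the polygenic scores under Hardy-Weinberg equilibrium
#'
#' For risk-allele dosages G_j ~ Binomial(2, p_j), independent across
#' variants, the non-weighted score sum(G_j) has mean sum(2 p_j) and variance
#' sum(2 p_j (1 - p_j)); the weighted score sum(beta_j G_j) has mean
#' sum(beta_j 2 p_j) and variance sum(beta_j^2 2 p_j (1 - p_j)), with
#' beta_j = log(odds_ratio_j). These moments serve as the oracle for the
#' genotype simulator and supply the analytic score standard deviation used
#' by the power calculation.
#'
#' @param catalog A `variant_catalog`.
#' @param weighted If `TRUE`, moments of the weighted score; otherwise of the
#'   plain risk-allele count.
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
score_moments <- function(catalog, weighted = FALSE) {
  stopifnot(inherits(catalog, "variant_catalog"))
  if (nrow(catalog) == 0) stop("empty catalog")
  p <- catalog$risk_allele_freq
  w <- if (weighted) catalog$weight else rep(1, nrow(catalog))
  c(mean = sum(w * 2 * p), variance = sum(w^2 * 2 * p * (1 - p)))
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("variant catalog:", nrow(x), "variants\n")
  note <- attr(x, "source_note")
  if (!is.null(note)) cat("source:", note, "\n")
  NextMethod()
}
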