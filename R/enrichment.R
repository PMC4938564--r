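#' Read gene sets in GMT format
#'
#' Thin wrapper over `fgsea::gmtPathways()`: one set per line, tab-separated
#' (set name, description, member genes).
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Read a variant-to-gene mapping file
#'
#' TSV with columns `rsid` and `gene`, one gene per variant. The packaged
#' best-effort reconstruction for the 94-variant catalog ships as
#' `extdata/variant_gene_map_synthetic.tsv`.
#'
#' @param path Path to the mapping TSV; defaults to the packaged file.
#' @return `data.frame` with `rsid` and `gene`.
#' @export
read_variant_gene_map <- function(path = system.file(
  "extdata", "variant_gene_map_synthetic.tsv", package = "toxprs")) {
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "gene") %in% names(m)))
  if (anyDuplicated(m$rsid)) stop("mapping assigns multiple genes to a variant")
  m
}

#' Map scanned variants to genes and rank by association p-value
#'
#' Each variant is assigned the single gene from `mapping`; where several
#' variants map to the same gene, the most significant (smallest p-value)
#' variant represents it, regardless of the direction of effect. Genes are
#' ranked by ascending p-value, ties broken by rsid lexicographic order.
#' Variants absent from the mapping are excluded with a warning.
#'
#' @param scan An `association_result` from [per_variant_scan()] (columns
#'   `term` = rsid and `p_value`), or any data frame with those columns.
#' @param mapping `data.frame` with `rsid` and `gene` (one gene per variant).
#' @return A `gene_ranking` list: `ranking` (data frame `gene`,
#'   `best_variant`, `p_value`, sorted) and `background` (all mapped genes).
#' @export
map_and_rank <- function(scan, mapping) {
  stopifnot(all(c("term", "p_value") %in% names(scan)),
            all(c("rsid", "gene") %in% names(mapping)))
  unmapped <- setdiff(scan$term, mapping$rsid)
  if (length(unmapped)) {
    warning("excluding variant(s) with no gene mapping: ",
            paste(unmapped, collapse = ", "))
  }
  d <- data.frame(rsid = scan$term, p_value = scan$p_value,
                  stringsAsFactors = FALSE)
  d <- d[d$rsid %in% mapping$rsid, , drop = FALSE]
  d$gene <- mapping$gene[match(d$rsid, mapping$rsid)]
  d <- d[order(d$p_value, d$rsid), , drop = FALSE]
  best <- d[!duplicated(d$gene), , drop = FALSE]
  ranking <- data.frame(gene = best$gene, best_variant = best$rsid,
                        p_value = best$p_value, row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 background = unique(mapping$gene[mapping$rsid %in% scan$term])),
            class = "gene_ranking")
}

#' Take the top fraction of a gene ranking
#'
#' Returns the first `floor(fraction * n)` genes of the ranked list (floor
#' convention: an even list of 76 genes gives 38, a list of 7 gives 3).
#'
#' @param ranking A `gene_ranking` from [map_and_rank()], or a data frame
#'   with a `gene` column already in rank order.
#' @param fraction Fraction in (0, 1]; default 0.5 (the top half).
#' @return Character vector of gene symbols.
#' @export
top_fraction <- function(ranking, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  genes <- if (inherits(ranking, "gene_ranking")) ranking$ranking$gene
           else ranking$gene
  utils::head(genes, floor(fraction * length(genes)))
}

#' Fisher overrepresentation of gene sets in a ranked top list
#'
#' For each gene set, intersects the set with the background universe and
#' tests whether the top list is enriched for it with a one-sided
#' hypergeometric upper-tail (Fisher) p-value on the 2x2 in-top x in-set
#' table. Bonferroni correction multiplies by the number of sets actually
#' tested (capped at 1). Sets with no background overlap are skipped and
#' recorded in attribute `skipped`.
#'
#' The background defaults to the full mapped gene list of the catalog (the
#' ranked list's own universe), not the genome.
#'
#' @param top_genes Character vector, a subset of `background`.
#' @param background Character vector: the gene universe.
#' @param gene_sets Named list of character vectors, e.g. from [read_gmt()].
#' @return An `enrichment_result` data frame sorted by `fisher_p`:
#'   `set_name`, `overlap_count`, `list_size`, `set_size_in_background`,
#'   `background_size`, `fisher_p`, `bonferroni_p`, `overlap_genes`
#'   (semicolon-joined).
#' @export
fisher_overrepresentation <- function(top_genes, background, gene_sets) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background universe")
  if (!all(top_genes %in% background)) {
    stop("top list contains genes outside the background universe")
  }
  top_genes <- unique(top_genes)
  rows <- list()
  skipped <- character(0)
  for (nm in names(gene_sets)) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    if (length(s) == 0) {
      skipped <- c(skipped, nm)
      next
    }
    hits <- intersect(top_genes, s)
    k <- length(hits)
    # P(X >= k), X ~ Hypergeom(set size, background minus set, list size)
    p <- stats::phyper(k - 1, length(s), length(background) - length(s),
                       length(top_genes), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set_name = nm, overlap_count = k,
                             list_size = length(top_genes),
                             set_size_in_background = length(s),
                             background_size = length(background),
                             fisher_p = p,
                             overlap_genes = paste(sort(hits), collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("skipped set(s) with no background overlap: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(rows)) {
    out <- data.frame(set_name = character(0), overlap_count = integer(0),
                      list_size = integer(0),
                      set_size_in_background = integer(0),
                      background_size = integer(0), fisher_p = numeric(0),
                      bonferroni_p = numeric(0), overlap_genes = character(0))
  } else {
    out <- do.call(rbind, rows)
    out$bonferroni_p <- pmin(1, out$fisher_p * nrow(out))
    out <- out[order(out$fisher_p, out$set_name),
               c("set_name", "overlap_count", "list_size",
                 "set_size_in_background", "background_size", "fisher_p",
                 "bonferroni_p", "overlap_genes")]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}
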