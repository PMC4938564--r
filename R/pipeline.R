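#' Read a dosage matrix from TSV or VCF
#'
#' TSV layout: first column `sample_id`, remaining columns one rsid each,
#' `NA` for missing, dosages in `[0, 2]`. The TSV orientation is trusted by
#' default; if `counted_alleles` (a named character vector, rsid -> counted
#' allele) is supplied, dosages whose counted allele differs from the catalog
#' risk allele are flipped `D -> 2 - D`.
#'
#' VCF input needs a per-genotype dosage field (`DS`); the dosage counts the
#' ALT allele. Records whose ALT equals the catalog risk allele are kept
#' as-is; records whose REF is the risk allele are flipped; records matching
#' neither allele are excluded with a warning. Strand-ambiguous (A/T, C/G)
#' variants are flagged with a warning in VCF mode.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param catalog A `variant_catalog` used to orient dosages.
#' @param counted_alleles Optional named character vector for TSV input.
#' @return Dosage matrix (samples x variants) oriented to the risk allele.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"), catalog,
                         counted_alleles = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "variant_catalog"))
  if (!file.exists(path)) stop("dosage file not found: ", path)
  g <- switch(format,
              tsv = read_dosages_tsv(path, catalog, counted_alleles),
              vcf = read_dosages_vcf(path, catalog))
  rng <- range(g, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2] in ", path)
  g
}

read_dosages_tsv <- function(path, catalog, counted_alleles) {
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("TSV must have a sample_id column")
  g <- as.matrix(x[setdiff(names(x), "sample_id")])
  storage.mode(g) <- "double"
  rownames(g) <- x$sample_id
  unknown <- setdiff(colnames(g), catalog$rsid)
  if (length(unknown)) {
    warning("excluding variant(s) absent from catalog: ",
            paste(unknown, collapse = ", "))
    g <- g[, setdiff(colnames(g), unknown), drop = FALSE]
  }
  if (!is.null(counted_alleles)) {
    risk <- catalog$risk_allele[match(colnames(g), catalog$rsid)]
    counted <- counted_alleles[colnames(g)]
    flip <- !is.na(counted) & counted != risk
    g[, flip] <- 2 - g[, flip, drop = FALSE]
  }
  g
}

read_dosages_vcf <- function(path, catalog) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  idx <- match(ids, catalog$rsid)
  keep <- !is.na(idx)
  if (any(!keep)) {
    warning("excluding VCF record(s) absent from catalog: ",
            paste(ids[!keep], collapse = ", "))
  }
  ds <- ds[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  risk <- catalog$risk_allele[idx[keep]]
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ambiguous <- paste0(pmin(ref, alt), pmax(ref, alt)) %in% c("AT", "CG")
  if (any(ambiguous)) {
    warning("strand-ambiguous allele pair(s): ",
            paste(fix[ambiguous, "ID"], collapse = ", "))
  }
  as_is <- alt == risk
  flip <- ref == risk & !as_is
  drop <- !(as_is | flip)
  if (any(drop)) {
    warning("allele mismatch beyond flip; excluding: ",
            paste(fix[drop, "ID"], collapse = ", "))
  }
  ds[flip, ] <- 2 - ds[flip, , drop = FALSE]
  ds <- ds[!drop, , drop = FALSE]
  g <- t(ds)
  colnames(g) <- fix[!drop, "ID"]
  g
}

#' Assemble a pipeline run configuration
#'
#' Either a `simulation` block (see [simulation_config()]) or a `dosage_path`
#' plus `phenotype_path` must be provided. Defaults reproduce the standard
#' analysis: QC thresholds of 5% variant missingness, 1% MAF, the 5%/1%
#' joint rule, Hardy-Weinberg p < 1e-5 and 10% sample missingness; a
#' per-variant scan threshold of 5e-4; top-50% gene ranking.
#'
#' @param catalog_path Path to the variant catalog TSV.
#' @param simulation Optional list of arguments for [simulation_config()].
#' @param dosage_path,dosage_format,phenotype_path Real-data inputs.
#' @param gmt_path,mapping_path Gene sets and variant-to-gene mapping for
#'   enrichment (`NULL` disables enrichment).
#' @param seed Base integer seed; per-stage seeds are derived from it.
#' @param qc,analysis Optional lists overriding QC thresholds
#'   (`variant_max_missing`, `min_maf`, `lowmaf`, `lowmaf_max_missing`,
#'   `hwe_p_min`, `sample_max_missing`) and analysis settings
#'   (`scan_alpha`, `top_fraction`, `power_mean_difference`,
#'   `power_case_fraction`, `power_alpha`).
#' @return A `run_config` list.
#' @export
run_config <- function(catalog_path = system.file("extdata",
                                                  "table1_catalog.tsv",
                                                  package = "toxprs"),
                       simulation = list(n_samples = 1676L),
                       dosage_path = NULL, dosage_format = "tsv",
                       phenotype_path = NULL,
                       gmt_path = system.file("extdata",
                                              "pathways_synthetic.gmt",
                                              package = "toxprs"),
                       mapping_path = system.file(
                         "extdata", "variant_gene_map_synthetic.tsv",
                         package = "toxprs"),
                       seed = 42L, qc = list(), analysis = list()) {
  if (is.null(simulation) && (is.null(dosage_path) ||
                              is.null(phenotype_path))) {
    stop("config needs either a 'simulation' block or both 'dosage_path' ",
         "and 'phenotype_path'")
  }
  for (p in c(catalog_path = catalog_path, dosage_path = dosage_path,
              phenotype_path = phenotype_path, gmt_path = gmt_path,
              mapping_path = mapping_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config path does not exist: ", p)
    }
  }
  qc_def <- list(variant_max_missing = 0.05, min_maf = 0.01, lowmaf = 0.05,
                 lowmaf_max_missing = 0.01, hwe_p_min = 1e-5,
                 sample_max_missing = 0.10)
  an_def <- list(scan_alpha = 5e-4, top_fraction = 0.5,
                 power_mean_difference = 0.1, power_case_fraction = 0.30,
                 power_alpha = 0.05)
  qc_def[names(qc)] <- qc
  an_def[names(analysis)] <- analysis
  stopifnot(all(unlist(qc_def) > 0))
  structure(list(catalog_path = catalog_path, simulation = simulation,
                 dosage_path = dosage_path, dosage_format = dosage_format,
                 phenotype_path = phenotype_path, gmt_path = gmt_path,
                 mapping_path = mapping_path, seed = as.integer(seed),
                 qc = qc_def, analysis = an_def),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates: catalog loading, dosage input (simulated or from file),
#' variant/sample QC, score computation, the 2x2 association table
#' ({non-weighted, weighted} x {unadjusted, adjusted}) for each available
#' phenotype, the per-variant scan, gene ranking and Fisher
#' overrepresentation, the analytic and simulated power summary, and the
#' survival linkage. All numeric outputs are written as TSV plus a JSON run
#' manifest (seed, config hash, package version); rerunning with an
#' identical config reproduces every output byte-identically.
#'
#' @param cfg A `run_config` (or path to a YAML file).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all result objects and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- pipeline_stage("catalog", load_catalog(cfg$catalog_path))

  simulated <- !is.null(cfg$simulation)
  if (simulated) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    scfg <- pipeline_stage("simulate", do.call(simulation_config, sim_args))
    sim <- pipeline_stage("simulate", simulate_cohort(catalog, scfg))
    g_raw <- sim$dosages
    cohort <- sim$cohort
  } else {
    g_raw <- pipeline_stage("read_dosages",
                            read_dosages(cfg$dosage_path, cfg$dosage_format,
                                         catalog))
    cohort <- pipeline_stage("read_phenotypes",
                             utils::read.delim(cfg$phenotype_path,
                                               comment.char = "#",
                                               stringsAsFactors = FALSE))
  }

  qc <- cfg$qc
  qcres <- pipeline_stage("qc", qc_fixpoint(
    g_raw, max_missing = qc$variant_max_missing, min_maf = qc$min_maf,
    lowmaf = qc$lowmaf, lowmaf_max_missing = qc$lowmaf_max_missing,
    hwe_p_min = qc$hwe_p_min, sample_max_missing = qc$sample_max_missing))
  g <- qcres$dosages

  if (!all(c("pc1", "pc2") %in% names(cohort)) && nrow(g) >= 2 &&
      ncol(g) >= 2) {
    pcs <- pipeline_stage("pca", compute_pcs(g, 2))
    cohort$pc1 <- pcs[match(cohort$sample_id, rownames(pcs)), 1]
    cohort$pc2 <- pcs[match(cohort$sample_id, rownames(pcs)), 2]
  }

  scores <- pipeline_stage("score", standardize(compute_scores(g, catalog)))

  phenos <- intersect(c("neutropenia", "neuropathy"),
                      sub("_grade$", "",
                          grep("_grade$", names(cohort), value = TRUE)))
  assoc <- list()
  scans <- list()
  for (ph in phenos) {
    for (kind in c("unweighted", "weighted")) {
      for (adj in c(FALSE, TRUE)) {
        key <- paste(ph, kind, if (adj) "adjusted" else "unadjusted",
                     sep = ".")
        assoc[[key]] <- pipeline_stage(
          "associate",
          cbind(phenotype = ph,
                fit_score_model(cohort, scores, ph, kind, adjusted = adj)))
      }
    }
    scans[[ph]] <- pipeline_stage(
      "scan", per_variant_scan(g, cohort, ph, adjusted = FALSE,
                               alpha = cfg$analysis$scan_alpha))
  }
  assoc_tab <- do.call(rbind, assoc)
  rownames(assoc_tab) <- NULL

  ranking <- NULL
  enrich <- NULL
  if (!is.null(cfg$gmt_path) && length(scans)) {
    mapping <- pipeline_stage("enrich", read_variant_gene_map(cfg$mapping_path))
    sets <- pipeline_stage("enrich", read_gmt(cfg$gmt_path))
    scan0 <- scans[[phenos[1]]]
    ranking <- pipeline_stage("enrich",
                              suppressWarnings(map_and_rank(scan0, mapping)))
    top <- top_fraction(ranking, cfg$analysis$top_fraction)
    enrich <- pipeline_stage(
      "enrich",
      suppressMessages(
        fisher_overrepresentation(top, ranking$background, sets)))
  }

  sd_w <- sqrt(unname(score_moments(catalog, weighted = TRUE)["variance"]))
  an <- cfg$analysis
  pow <- pipeline_stage("power", {
    rows <- lapply(phenos, function(ph) {
      n <- sum(!is.na(cohort[[paste0(ph, "_grade")]]))
      data.frame(phenotype = ph, n_total = n,
                 case_fraction = an$power_case_fraction,
                 mean_difference = an$power_mean_difference,
                 score_sd = sd_w, alpha = an$power_alpha,
                 analytic_power = analytic_power(
                   n, an$power_case_fraction, an$power_mean_difference,
                   sd_w, an$power_alpha),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  surv <- NULL
  if (all(c("rfs_time", "rfs_event") %in% names(cohort))) {
    surv <- pipeline_stage("survive",
                           fit_survival(cohort, scores,
                                        adjust_for_neutropenia = FALSE))
  }

  write_tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(qcres$variant_report$variants, "qc_variants.tsv")
  write_tsv(qcres$sample_report$samples, "qc_samples.tsv")
  write_tsv(scores, "scores.tsv")
  write_tsv(assoc_tab, "associations.tsv")
  for (ph in names(scans)) {
    write_tsv(scans[[ph]], paste0("variant_scan_", ph, ".tsv"))
  }
  if (!is.null(ranking)) write_tsv(ranking$ranking, "gene_ranking.tsv")
  if (!is.null(enrich)) write_tsv(enrich, "enrichment.tsv")
  write_tsv(pow, "power.tsv")
  if (!is.null(surv)) {
    write_tsv(data.frame(surv[c("hazard_ratio", "ci_low", "ci_high",
                                "p_value", "hr_per_k", "ci_low_per_k",
                                "ci_high_per_k", "per_k_alleles", "n_used",
                                "n_events")]),
              "survival.tsv")
  }
  manifest <- list(
    package = "toxprs",
    version = as.character(utils::packageVersion("toxprs")),
    seed = cfg$seed,
    simulated_input = simulated,
    config_hash = config_hash(cfg),
    n_samples = nrow(g), n_variants = ncol(g),
    phenotypes = phenos)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(catalog = catalog, dosages = g, cohort = cohort,
                 qc = qcres, scores = scores, associations = assoc_tab,
                 scans = scans, ranking = ranking, enrichment = enrich,
                 power = pow, survival = surv, out_dir = out_dir))
}

# Stable hash of the configuration for the run manifest.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # tiny polynomial rolling hash over the serialized config; avoids a
  # digest dependency
  h <- 0
  for (b in as.integer(charToRaw(as.character(s)))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
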