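#' Packaged MAN2B1 (alpha-mannosidosis) inputs
#'
#' The package ships the published MAN2B1 analysis inputs as plain-text
#' fixtures: the 81 pathogenic / likely pathogenic gnomAD v2.1.1 variants
#' with per-population allele frequencies and minimal evidence codes
#' consistent with each variant's published classification; the
#' per-population disease-allele counts and cohort sizes under the three
#' classification schemes (including the Korean KOVA and KRGDB reference
#' cohorts, whose counts are back-derived from the published carrier
#' frequencies); and the run configuration tying them together.
#'
#' @return `man2b1_config()` returns the path to the packaged YAML
#'   configuration; `man2b1_variants()` the packaged variant table as a
#'   `variant_tbl`; `man2b1_cohort_counts()` the cohort-counts data frame.
#' @name man2b1_fixtures
NULL

#' @rdname man2b1_fixtures
#' @export
man2b1_config <- function() {
  system.file("extdata", "man2b1_config.yaml", package = "carrierfreq",
              mustWork = TRUE)
}

#' @rdname man2b1_fixtures
#' @export
man2b1_variants <- function() {
  cfg <- run_config(man2b1_config())
  read_variant_table(cfg$variant_table, cfg$schema)
}

#' @rdname man2b1_fixtures
#' @export
man2b1_cohort_counts <- function() {
  cfg <- run_config(man2b1_config())
  read_cohort_counts(cfg$cohort_counts)
}

#' Load and validate a pipeline run configuration
#'
#' Reads a declarative YAML configuration naming the variant table, its
#' schema, the cohort registry (population label -> sample size), the QC
#' flags to exclude, the classification schemes, pooling groups and
#' projection parameters. Relative paths are resolved against the
#' configuration file's directory. Validation happens before any I/O:
#' every pooling-group member must exist in the cohort registry or the
#' cohort-counts table, and the registry must be non-empty.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`.
#' @export
run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)

  registry <- unlist(raw$cohort_registry)
  if (is.null(registry) || length(registry) == 0L)
    stop("config error: empty cohort_registry", call. = FALSE)

  sch <- raw$schema
  schema <- variant_schema(
    hgvs_c = sch$hgvs_c %||% "hgvs_c",
    hgvs_p = sch$hgvs_p %||% "hgvs_p",
    populations = unlist(sch$populations),
    qc_flags = sch$qc_flags, evidence = sch$evidence,
    revel = sch$revel, spliceai = sch$spliceai,
    clinvar = sch$clinvar, hgmd = sch$hgmd)

  counts_path <- resolve(raw$cohort_counts)
  known_pops <- names(registry)
  if (!is.null(counts_path)) {
    counts <- read_cohort_counts(counts_path)
    known_pops <- union(known_pops, counts$population)
  }
  for (grp in names(raw$pooling)) {
    members <- unlist(raw$pooling[[grp]])
    bad <- setdiff(members, known_pops)
    if (length(bad))
      stop("config error: pooling group '", grp,
           "' references unknown cohort(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  thr <- raw$thresholds
  thresholds <- if (is.null(thr)) threshold_config() else
    do.call(threshold_config, thr)

  structure(list(
    gene = raw$gene, transcript = raw$transcript,
    variant_table = resolve(raw$variant_table),
    cohort_counts = counts_path,
    schema = schema,
    cohort_registry = registry,
    excluded_qc_flags = unlist(raw$excluded_qc_flags) %||%
      c("InbreedingCoeff", "AC0", "RF"),
    schemes_from_variants = unlist(raw$schemes_from_variants) %||% "acmg",
    thresholds = thresholds,
    pooling = raw$pooling,
    projection = raw$projection,
    seed = raw$seed
  ), class = "run_config")
}

# Cohort-counts table: database, population, scheme, n_individuals,
# disease_allele_count.
read_cohort_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "scheme", "n_individuals", "disease_allele_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort-counts table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(df$database)) df$database <- "counts"
  df
}

#' Run the full carrier-frequency analysis
#'
#' Executes the pipeline stages in order: read the variant table, apply QC
#' filters, classify under each requested scheme, aggregate per-population
#' disease-allele counts, fit carrier-frequency / incidence estimates,
#' pool the declared cohort groups, project the population burden, and
#' summarise the variant spectrum. Estimates for schemes with per-variant
#' annotations come from the variant table; cohorts listed in the
#' cohort-counts table (other schemes, external databases) are estimated
#' from their counts directly. Re-running on identical inputs produces
#' identical reports.
#'
#' @param config A [run_config()] or the path to one.
#' @param output_dir Optional directory; when given, TSV/JSON/text reports
#'   are written there.
#' @param level Confidence level for all intervals.
#' @return An object of class `carrier_report`: list with `variants`
#'   (QC-filtered table), `masks` (per scheme), `estimates` (list of
#'   `carrier_estimate`), `table1` (rendered lines with a `data`
#'   attribute), `pooled` (list of `carrier_estimate`), `projection`,
#'   `spectrum`, `ranking` and `log` (record counts per stage).
#' @export
run_pipeline <- function(config, output_dir = NULL, level = 0.95) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- list()

  variants <- read_variant_table(config$variant_table, config$schema)
  log$input_records <- nrow(variants)
  variants <- apply_qc_filters(variants, config$excluded_qc_flags)
  log$qc_removed <- log$input_records - nrow(variants)
  log$records_kept <- nrow(variants)

  registry <- config$cohort_registry
  masks <- lapply(stats::setNames(nm = config$schemes_from_variants),
                  function(s)
                    disease_allele_mask(variants, s, config$thresholds))

  estimates <- list()
  for (s in names(masks)) {
    for (lab in names(registry)) {
      x <- sum(population_allele_counts(variants[masks[[s]], , drop = FALSE],
                                        lab, registry[[lab]]))
      estimates <- c(estimates, list(
        carrier_fit(cohort(lab, registry[[lab]], x, s), level = level)))
    }
  }

  counts <- if (!is.null(config$cohort_counts))
    read_cohort_counts(config$cohort_counts) else NULL
  if (!is.null(counts)) {
    # rows already recomputed from the variant table are not duplicated
    dup <- counts$scheme %in% names(masks) &
      counts$population %in% names(registry)
    for (i in which(!dup)) {
      estimates <- c(estimates, list(
        carrier_fit(cohort(counts$population[[i]],
                           counts$n_individuals[[i]],
                           counts$disease_allele_count[[i]],
                           counts$scheme[[i]]), level = level)))
    }
  }
  log$cohorts_estimated <- length(estimates)

  by_label <- function(lab, scheme) {
    for (e in estimates)
      if (e$cohort$label == lab && e$cohort$scheme == scheme) return(e$cohort)
    stop("no estimated cohort named '", lab, "' under scheme ", scheme,
         call. = FALSE)
  }
  pooled <- list()
  for (grp in names(config$pooling)) {
    members <- lapply(unlist(config$pooling[[grp]]), by_label,
                      scheme = names(masks)[[1L]] %||% "acmg")
    pooled[[grp]] <- carrier_fit(pool_cohorts(members, grp), level = level)
  }

  projection <- NULL
  if (!is.null(config$projection)) {
    pr <- config$projection
    target <- if (!is.null(pr$cohort) && pr$cohort %in% names(pooled))
      pooled[[pr$cohort]] else estimates[[1L]]
    # projections quote the reported 2-decimal-percent carrier frequency
    cf_reported <- round(100 * target$carrier_frequency, 2) / 100
    projection <- project_burden(cf_reported, target$incidence_denominator,
                                 pr$population_size, pr$annual_births)
  }

  first_scheme <- names(masks)[[1L]] %||% "acmg"
  spectrum <- ranking <- NULL
  if (length(masks) && length(registry)) {
    global_lab <- names(registry)[[1L]]
    spectrum <- consequence_spectrum(variants, masks[[first_scheme]],
                                     global_lab, registry[[global_lab]])
    ranking <- rank_disease_alleles(variants, masks[[first_scheme]],
                                    global_lab, registry[[global_lab]])
  }

  table1 <- render_table1(c(estimates, unname(pooled)))
  report <- structure(list(variants = variants, masks = masks,
                           estimates = estimates, table1 = table1,
                           pooled = pooled, projection = projection,
                           spectrum = spectrum, ranking = ranking,
                           log = log),
                      class = "carrier_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.carrier_report <- function(x, ...) {
  cat("Carrier-frequency analysis report\n")
  cat(sprintf("  records: %d read, %d removed by QC, %d analysed\n",
              x$log$input_records, x$log$qc_removed, x$log$records_kept))
  cat(x$table1, sep = "\n")
  if (!is.null(x$projection)) print(x$projection)
  invisible(x)
}

# TSV + JSON + aligned-text renderings of a report; JSON numbers unrounded.
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  df <- attr(report$table1, "data")
  utils::write.table(df, file.path(output_dir, "table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$table1, file.path(output_dir, "table1.txt"))
  if (!is.null(report$spectrum))
    utils::write.table(as.data.frame(report$spectrum),
                       file.path(output_dir, "spectrum.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$ranking))
    utils::write.table(report$ranking,
                       file.path(output_dir, "ranked_alleles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    log = report$log,
    estimates = lapply(report$estimates, unclass_estimate),
    pooled = lapply(report$pooled, unclass_estimate),
    projection = if (!is.null(report$projection)) unclass(report$projection),
    spectrum = if (!is.null(report$spectrum)) as.data.frame(report$spectrum))
  jsonlite::write_json(payload, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(output_dir)
}

unclass_estimate <- function(e) {
  list(population = e$cohort$label, scheme = e$cohort$scheme,
       n_individuals = e$cohort$n_individuals,
       disease_allele_count = e$cohort$disease_allele_count,
       carrier_frequency = e$carrier_frequency,
       cf_lower = e$cf_ci$lower, cf_upper = e$cf_ci$upper,
       q = e$q, incidence = e$incidence,
       incidence_denominator = e$incidence_denominator,
       incidence_denominator_ci = e$incidence_denominator_ci,
       level = e$level)
}
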