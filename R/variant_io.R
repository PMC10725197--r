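#' Declare the column layout of a variant export
#'
#' A schema maps columns of a tabular per-gene export (gnomAD-style) onto
#' the fields the package understands, and declares which columns carry
#' per-population allele frequencies.
#'
#' @param hgvs_c Column holding the coding-DNA HGVS change (mandatory).
#' @param hgvs_p Column holding the protein HGVS change (may contain `"p.?"`).
#' @param populations Named character vector: population label -> column name
#'   of that population's allele frequency. At least one entry is required.
#' @param qc_flags Optional column of QC filter flags (comma/semicolon/pipe
#'   separated within a cell; empty means no flags).
#' @param evidence Optional column of semicolon-separated ACMG/AMP evidence
#'   codes (e.g. `"PVS1;PM2"`); a code may carry an explicit strength as
#'   `"PVS1:moderate"`.
#' @param revel,spliceai Optional columns of REVEL and SpliceAI (max delta)
#'   scores in `[0, 1]`.
#' @param clinvar,hgmd Optional columns of ClinVar (`PV`, `LPV`, `VUS`, `LB`,
#'   `BV`) and HGMD (`DM`, `other`) assertions; empty cells mean absent.
#' @return An object of class `variant_schema`.
#' @seealso [read_variant_table()]
#' @export
variant_schema <- function(hgvs_c = "hgvs_c", hgvs_p = "hgvs_p",
                           populations,
                           qc_flags = NULL, evidence = NULL,
                           revel = NULL, spliceai = NULL,
                           clinvar = NULL, hgmd = NULL) {
  if (missing(populations) || length(populations) == 0L)
    stop("schema error: at least one population column must be declared",
         call. = FALSE)
  populations <- unlist(populations)
  if (is.null(names(populations)) || any(!nzchar(names(populations))))
    stop("schema error: 'populations' must be a named vector (label -> column)",
         call. = FALSE)
  structure(
    list(hgvs_c = hgvs_c, hgvs_p = hgvs_p, populations = populations,
         qc_flags = qc_flags, evidence = evidence,
         revel = revel, spliceai = spliceai,
         clinvar = clinvar, hgmd = hgmd),
    class = "variant_schema"
  )
}

#' Read a tabular variant export
#'
#' Reads a delimiter-separated per-gene variant table (tab or comma,
#' auto-detected from the header line) into a `variant_tbl` data frame with
#' one row per variant. Optional columns absent from the schema or the file
#' yield "absent" values (`NA` scores, empty flag sets, `"absent"`
#' assertions). Row order is preserved.
#'
#' @param source Path to the file, or a character vector of lines.
#' @param schema A [variant_schema()] describing the columns.
#' @return A data frame of class `variant_tbl` with columns `hgvs_c`,
#'   `hgvs_p`, `qc_flags` (list of character vectors), `revel`,
#'   `spliceai_max_delta`, `clinvar_class`, `hgmd_class`, `evidence`, and one
#'   allele-frequency column per declared population, named by its label.
#'   The population labels are kept in `attr(x, "populations")`.
#' @export
read_variant_table <- function(source, schema) {
  stopifnot(inherits(schema, "variant_schema"))
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source
  if (length(lines) == 0L)
    stop("empty input: no header line", call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           quote = "\"", colClasses = "character",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)

  need <- c(schema$hgvs_c, unname(schema$populations))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("schema error: mandatory column(s) missing from input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  get_col <- function(col) if (!is.null(col) && col %in% names(raw))
    raw[[col]] else rep(NA_character_, n)

  hgvs_c <- trimws(get_col(schema$hgvs_c))
  if (n > 0L && any(!nzchar(hgvs_c) | is.na(hgvs_c)))
    stop("row ", which(!nzchar(hgvs_c) | is.na(hgvs_c))[1L],
         ": empty hgvs_c", call. = FALSE)
  hgvs_p <- trimws(get_col(schema$hgvs_p))
  hgvs_p[is.na(hgvs_p) | !nzchar(hgvs_p)] <- "p.?"

  parse_score <- function(col, what) {
    v <- suppressWarnings(as.numeric(get_col(col)))
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop("row ", bad[1L], ": ", what, " score outside [0, 1]: ",
           v[bad[1L]], call. = FALSE)
    v
  }

  out <- data.frame(hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$qc_flags <- parse_flag_sets(get_col(schema$qc_flags))
  out$revel <- parse_score(schema$revel, "REVEL")
  out$spliceai_max_delta <- parse_score(schema$spliceai, "SpliceAI")

  norm_assert <- function(col, allowed) {
    v <- toupper(trimws(get_col(col)))
    v[is.na(v) | !nzchar(v)] <- "absent"
    v[v == "ABSENT"] <- "absent"
    keep <- v %in% c(allowed, "absent")
    v[!keep] <- "other"
    v
  }
  out$clinvar_class <- norm_assert(schema$clinvar, c("PV", "LPV", "VUS", "LB", "BV"))
  out$hgmd_class <- norm_assert(schema$hgmd, "DM")
  ev <- get_col(schema$evidence)
  ev[is.na(ev)] <- ""
  out$evidence <- ev

  for (lab in names(schema$populations)) {
    col <- schema$populations[[lab]]
    txt <- trimws(raw[[col]])
    af <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(af) | af < 0 | af > 1)
    if (length(bad))
      stop("row ", bad[1L], ": malformed allele frequency in column '",
           col, "': '", txt[bad[1L]], "'", call. = FALSE)
    out[[lab]] <- af
  }

  attr(out, "populations") <- names(schema$populations)
  class(out) <- c("variant_tbl", "data.frame")
  out
}

#' @export
`[.variant_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "populations") <- intersect(attr(x, "populations"), names(out))
    class(out) <- c("variant_tbl", "data.frame")
  }
  out
}

# Split "AC0;RF" / "AC0,RF" / "AC0|RF" cells into character vectors.
parse_flag_sets <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, "[;,|]"), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Write a variant table back to disk
#'
#' Serialises a `variant_tbl` in the same tab-separated dialect
#' [read_variant_table()] reads, with flag sets re-joined by `";"`.
#'
#' @param variants A `variant_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  stopifnot(inherits(variants, "variant_tbl"))
  flat <- as.data.frame(variants, check.names = FALSE)
  flat$qc_flags <- vapply(variants$qc_flags, paste, "", collapse = ";")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop variants failing database QC filters
#'
#' Removes records carrying any of the excluded site-level QC flags. The
#' gnomAD default excludes variants flagged `InbreedingCoeff`, `AC0` or `RF`.
#' Idempotent; never increases the record count. The number of removed
#' records is reported via `message()`.
#'
#' @param variants A `variant_tbl`.
#' @param excluded_flags Character vector of flag names whose presence
#'   excludes a record.
#' @return The filtered `variant_tbl`.
#' @export
apply_qc_filters <- function(variants,
                             excluded_flags = c("InbreedingCoeff", "AC0", "RF")) {
  stopifnot(inherits(variants, "variant_tbl"))
  if (length(excluded_flags) == 0L) {
    message("QC filter: 0 of ", nrow(variants), " records removed")
    return(variants)
  }
  hit <- vapply(variants$qc_flags,
                function(fl) any(fl %in% excluded_flags), NA)
  unknown <- setdiff(unique(unlist(variants$qc_flags)), excluded_flags)
  if (length(unknown))
    message("QC filter: ignoring unrecognised flag(s): ",
            paste(unknown, collapse = ", "))
  message("QC filter: ", sum(hit), " of ", nrow(variants),
          " records removed")
  variants[!hit, , drop = FALSE]
}

#' Classify an HGVS change into a molecular consequence
#'
#' Assigns each variant exactly one consequence class from its HGVS protein
#' and coding-DNA descriptions, by precedence: frameshift (`fs` in the
#' protein change), nonsense (single residue to a stop, `*`), synonymous
#' (protein change ending `=`), splicing (`p.?` with an intronic offset such
#' as `+1` or `-2` in the coding change), then missense (single
#' residue-to-residue substitution). Whitespace inside printed HGVS strings
#' (a typographic artifact of published tables) is stripped before parsing.
#' Anything matching no rule is classed `other` with a warning, never an
#' error.
#'
#' @param hgvs_c,hgvs_p Character vectors of equal length; `hgvs_c` must be
#'   non-empty, `hgvs_p` may be `"p.?"`.
#' @return A factor with levels `missense`, `nonsense`, `frameshift`,
#'   `splicing`, `synonymous`, `other`.
#' @examples
#' parse_consequence("c.2248C>T", "p.(Arg750Trp)")   # missense
#' parse_consequence("c.1830 + 1G>C", "p.?")          # splicing
#' @export
parse_consequence <- function(hgvs_c, hgvs_p) {
  stopifnot(length(hgvs_c) == length(hgvs_p))
  if (any(is.na(hgvs_c) | !nzchar(hgvs_c)))
    stop("hgvs_c must be non-empty", call. = FALSE)
  cc <- gsub("[[:space:]]+", "", hgvs_c)
  pp <- gsub("[[:space:]]+", "", hgvs_p)
  pp[is.na(pp) | !nzchar(pp)] <- "p.?"

  out <- rep("other", length(cc))
  # lowest precedence assigned first, then overwritten
  out[grepl("^p\\.\\(?[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}\\)?$", pp)] <- "missense"
  out[pp == "p.?" & grepl("[0-9]+[+-][0-9]+", cc)] <- "splicing"
  out[grepl("=\\)?$", pp)] <- "synonymous"
  out[grepl("^p\\.\\(?[A-Z][a-z]{2}[0-9]+\\*\\)?$", pp)] <- "nonsense"
  out[grepl("fs", pp, fixed = TRUE)] <- "frameshift"

  if (any(out == "other"))
    warning(sum(out == "other"),
            " variant(s) matched no consequence rule; classed 'other'",
            call. = FALSE)
  factor(out, levels = consequence_levels())
}

consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "splicing", "synonymous", "other")
}

# TRUE where the coding change touches a canonical splice position (+1/+2 or
# -1/-2 intronic offset).
is_canonical_splice <- function(hgvs_c) {
  cc <- gsub("[[:space:]]+", "", hgvs_c)
  grepl("[0-9]+[+-][12]([^0-9]|$)", cc)
}

#' Recover an integer allele count from a printed allele frequency
#'
#' Published tables print allele frequencies to a few significant figures;
#' the underlying integer allele count is recovered as
#' `round(af * allele_number)` with half-away-from-zero rounding. By default
#' the allele number is the maximal `2 * n_individuals` (per-variant allele
#' numbers vary with coverage but are rarely printed).
#'
#' @param allele_frequency Numeric vector of frequencies in `[0, 1]`.
#' @param n_individuals Number of (diploid) individuals in the cohort.
#' @param allele_number Number of genotyped chromosomes; defaults to
#'   `2 * n_individuals`.
#' @return Integer vector of allele counts.
#' @examples
#' reconstruct_allele_count(2.35e-4, 125748)  # 59
#' @export
reconstruct_allele_count <- function(allele_frequency, n_individuals,
                                     allele_number = 2 * n_individuals) {
  if (any(is.na(allele_frequency)) || any(allele_frequency < 0) ||
      any(allele_frequency > 1))
    stop("allele_frequency must lie in [0, 1]", call. = FALSE)
  if (any(allele_number <= 0))
    stop("allele_number must be positive", call. = FALSE)
  as.integer(floor(allele_frequency * allele_number + 0.5))
}

# Reconstructed allele counts for one population column of a variant_tbl.
population_allele_counts <- function(variants, population, n_individuals) {
  if (!population %in% attr(variants, "populations"))
    stop("unknown population label: ", population, call. = FALSE)
  reconstruct_allele_count(variants[[population]], n_individuals)
}
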