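#' @importFrom stats setNames
NULL

# Catalogue of the 2015 ACMG/AMP evidence codes with their side and
# intrinsic strength.
acmg_code_table <- function() {
  path_codes <- c("PVS1",
                  paste0("PS", 1:4),
                  paste0("PM", 1:6),
                  paste0("PP", 1:5))
  ben_codes <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  strength <- c("very_strong",
                rep("strong", 4), rep("moderate", 6), rep("supporting", 5),
                "stand_alone", rep("strong", 4), rep("supporting", 7))
  data.frame(code = c(path_codes, ben_codes),
             side = rep(c("pathogenic", "benign"),
                        c(length(path_codes), length(ben_codes))),
             strength = strength,
             stringsAsFactors = FALSE)
}

acmg_strengths <- function() {
  c("stand_alone", "very_strong", "strong", "moderate", "supporting")
}

#' Build a set of ACMG/AMP evidence codes
#'
#' @param codes Character vector of evidence codes (e.g. `c("PVS1", "PM2")`).
#'   A code may carry an explicit strength override as `"CODE:strength"`
#'   (ClinGen-style strength modification, e.g. `"PVS1:moderate"`); the
#'   default is the code's intrinsic strength (PVS very strong, PS strong,
#'   PM moderate, PP supporting, BA stand-alone, BS strong, BP supporting).
#' @param provenance `"manual"` or `"auto"`, recycled across codes.
#' @return An object of class `evidence_set`: a data frame with columns
#'   `code`, `side`, `strength`, `provenance`. Duplicate codes are an error.
#' @export
evidence_set <- function(codes = character(), provenance = "manual") {
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0L) {
    out <- data.frame(code = character(), side = character(),
                      strength = character(), provenance = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("evidence_set", "data.frame")
    return(out)
  }
  parts <- strsplit(trimws(codes), ":", fixed = TRUE)
  code <- toupper(vapply(parts, `[`, "", 1L))
  override <- vapply(parts, function(p) if (length(p) > 1L) tolower(p[[2L]]) else NA_character_, "")
  cat_tbl <- acmg_code_table()
  idx <- match(code, cat_tbl$code)
  if (anyNA(idx))
    stop("unknown evidence code(s): ",
         paste(code[is.na(idx)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(code))
    stop("duplicate evidence code(s): ",
         paste(unique(code[duplicated(code)]), collapse = ", "),
         call. = FALSE)
  strength <- ifelse(is.na(override), cat_tbl$strength[idx], override)
  if (!all(strength %in% acmg_strengths()))
    stop("unknown strength override(s): ",
         paste(setdiff(strength, acmg_strengths()), collapse = ", "),
         call. = FALSE)
  out <- data.frame(code = code, side = cat_tbl$side[idx],
                    strength = strength,
                    provenance = rep_len(provenance, length(code)),
                    stringsAsFactors = FALSE)
  class(out) <- c("evidence_set", "data.frame")
  out
}

# Parse a semicolon-separated evidence cell ("PVS1;PM2") into an evidence_set.
parse_evidence <- function(x, provenance = "manual") {
  evidence_set(trimws(strsplit(x %||% "", ";")[[1L]]), provenance)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

# Merge two evidence sets; on a code collision the first set wins.
merge_evidence <- function(a, b) {
  keep <- !(b$code %in% a$code)
  out <- rbind(as.data.frame(a), as.data.frame(b)[keep, , drop = FALSE])
  class(out) <- c("evidence_set", "data.frame")
  out
}

#' The ACMG/AMP 2015 combining rules as a data-driven clause table
#'
#' Each row is one clause of the guideline's combining rules: the minimum
#' number of evidence codes per strength (counted on the clause's side)
#' that is sufficient for the clause's classification. The table is plain
#' data so alternative guideline versions can be swapped in.
#'
#' @return A data frame with columns `class`, `side`, `stand_alone`,
#'   `very_strong`, `strong`, `moderate`, `supporting`.
#' @export
acmg_rule_table <- function() {
  clause <- function(class, side, sa = 0, vs = 0, s = 0, m = 0, p = 0) {
    data.frame(class = class, side = side, stand_alone = sa,
               very_strong = vs, strong = s, moderate = m, supporting = p,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # Pathogenic
    clause("pathogenic", "pathogenic", vs = 1, s = 1),
    clause("pathogenic", "pathogenic", vs = 1, m = 2),
    clause("pathogenic", "pathogenic", vs = 1, m = 1, p = 1),
    clause("pathogenic", "pathogenic", vs = 1, p = 2),
    clause("pathogenic", "pathogenic", s = 2),
    clause("pathogenic", "pathogenic", s = 1, m = 3),
    clause("pathogenic", "pathogenic", s = 1, m = 2, p = 2),
    clause("pathogenic", "pathogenic", s = 1, m = 1, p = 4),
    # Likely pathogenic
    clause("likely_pathogenic", "pathogenic", vs = 1, m = 1),
    clause("likely_pathogenic", "pathogenic", s = 1, m = 1),
    clause("likely_pathogenic", "pathogenic", s = 1, p = 2),
    clause("likely_pathogenic", "pathogenic", m = 3),
    clause("likely_pathogenic", "pathogenic", m = 2, p = 2),
    clause("likely_pathogenic", "pathogenic", m = 1, p = 4),
    # Benign
    clause("benign", "benign", sa = 1),
    clause("benign", "benign", s = 2),
    # Likely benign
    clause("likely_benign", "benign", s = 1, p = 1),
    clause("likely_benign", "benign", p = 2)
  ))
}

classification_levels <- function() {
  c("pathogenic", "likely_pathogenic", "uncertain_significance",
    "likely_benign", "benign")
}

#' Combine evidence codes into a five-tier classification
#'
#' Applies the ACMG/AMP 2015 combining rules to an evidence set. Sets
#' containing both pathogenic-side and benign-side codes are conflicting
#' evidence and classify as `uncertain_significance` (the guideline's
#' default; no arbitration is attempted). Otherwise the strongest satisfied
#' clause of [acmg_rule_table()] on the active side decides; a set
#' satisfying no clause is `uncertain_significance`.
#'
#' @param evidence An `evidence_set`, or a character vector of codes passed
#'   through [evidence_set()].
#' @param rules A clause table in the shape of [acmg_rule_table()].
#' @return One of `"pathogenic"`, `"likely_pathogenic"`,
#'   `"uncertain_significance"`, `"likely_benign"`, `"benign"`.
#' @examples
#' combine_evidence(c("PVS1", "PM2"))  # likely_pathogenic
#' combine_evidence(c("PVS1", "PS1"))  # pathogenic
#' @export
combine_evidence <- function(evidence, rules = acmg_rule_table()) {
  if (!inherits(evidence, "evidence_set")) evidence <- evidence_set(evidence)
  sides <- unique(evidence$side)
  if (length(sides) == 0L) return("uncertain_significance")
  if (length(sides) > 1L) return("uncertain_significance")

  counts <- table(factor(evidence$strength, levels = acmg_strengths()))
  active <- rules[rules$side == sides, , drop = FALSE]
  ok <- apply(active[, acmg_strengths(), drop = FALSE], 1L,
              function(mins) all(counts >= mins))
  if (!any(ok)) return("uncertain_significance")
  fired <- active$class[ok]
  # strongest satisfied clause wins on either side
  for (cls in c("pathogenic", "likely_pathogenic", "benign", "likely_benign"))
    if (cls %in% fired) return(cls)
  "uncertain_significance"
}

#' Default score thresholds for computational evidence
#'
#' Thresholds governing the automatically assigned codes: PP3 requires
#' REVEL at or above `revel_pp3_min` (or, for splice-affecting variants,
#' SpliceAI max delta at or above `spliceai_pp3_min`); BP4 requires REVEL at
#' or below `revel_bp4_max` with no SpliceAI signal; PM2 requires the
#' maximum per-population allele frequency below `pm2_popmax_max`.
#'
#' @param revel_pp3_min,revel_bp4_max,spliceai_pp3_min,pm2_popmax_max
#'   Numeric thresholds in `[0, 1]`; `revel_bp4_max` must be below
#'   `revel_pp3_min`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(revel_pp3_min = 0.75, revel_bp4_max = 0.25,
                             spliceai_pp3_min = 0.2, pm2_popmax_max = 1e-4) {
  vals <- c(revel_pp3_min, revel_bp4_max, spliceai_pp3_min, pm2_popmax_max)
  if (any(vals < 0) || any(vals > 1))
    stop("all thresholds must lie in [0, 1]", call. = FALSE)
  if (revel_bp4_max >= revel_pp3_min)
    stop("revel_bp4_max must be below revel_pp3_min", call. = FALSE)
  structure(list(revel_pp3_min = revel_pp3_min,
                 revel_bp4_max = revel_bp4_max,
                 spliceai_pp3_min = spliceai_pp3_min,
                 pm2_popmax_max = pm2_popmax_max),
            class = "threshold_config")
}

#' Assign computational evidence codes to one variant
#'
#' Applies the automatable predicates: PVS1 for null variants (nonsense,
#' frameshift, or splicing at a canonical +/-1/2 position); PM2 for absence
#' or extreme rarity across populations; PP3/BP4 from REVEL and SpliceAI
#' scores per the [threshold_config()]. Manually supplied codes are merged
#' in with provenance `"manual"` and win on collision. Absent scores simply
#' contribute no code.
#'
#' @param consequence One of the [parse_consequence()] classes.
#' @param popmax_af Maximum allele frequency across the populations in which
#'   the variant was looked up (use 0 if unobserved).
#' @param hgvs_c Coding change; used to recognise canonical splice positions.
#' @param revel,spliceai_max_delta Optional scores in `[0, 1]` (`NA` = absent).
#' @param manual An `evidence_set` (or character codes) supplied alongside
#'   the variant.
#' @param thresholds A [threshold_config()].
#' @return An `evidence_set`.
#' @export
assign_computational_evidence <- function(consequence, popmax_af,
                                          hgvs_c = "",
                                          revel = NA_real_,
                                          spliceai_max_delta = NA_real_,
                                          manual = evidence_set(),
                                          thresholds = threshold_config()) {
  consequence <- as.character(consequence)
  codes <- character()
  null_variant <- consequence %in% c("nonsense", "frameshift") ||
    (consequence == "splicing" && is_canonical_splice(hgvs_c))
  if (null_variant) codes <- c(codes, "PVS1")
  if (popmax_af < thresholds$pm2_popmax_max) codes <- c(codes, "PM2")

  splice_relevant <- consequence == "splicing"
  pp3 <- (!is.na(revel) && revel >= thresholds$revel_pp3_min) ||
    (splice_relevant && !is.na(spliceai_max_delta) &&
       spliceai_max_delta >= thresholds$spliceai_pp3_min)
  bp4 <- !is.na(revel) && revel <= thresholds$revel_bp4_max &&
    (is.na(spliceai_max_delta) ||
       spliceai_max_delta < thresholds$spliceai_pp3_min)
  if (pp3) codes <- c(codes, "PP3")
  if (bp4) codes <- c(codes, "BP4")

  if (!inherits(manual, "evidence_set")) manual <- evidence_set(manual)
  merge_evidence(manual, evidence_set(codes, provenance = "auto"))
}

#' Classify every variant of a table
#'
#' Runs [assign_computational_evidence()] (merging any packaged evidence
#' column) and [combine_evidence()] across a `variant_tbl`.
#'
#' @param variants A `variant_tbl`.
#' @param thresholds A [threshold_config()].
#' @param auto Assign computational codes in addition to the table's
#'   `evidence` column? With `auto = FALSE` only packaged codes are used.
#' @return Character vector of five-tier classifications, one per record.
#' @export
classify_variants <- function(variants, thresholds = threshold_config(),
                              auto = TRUE) {
  stopifnot(inherits(variants, "variant_tbl"))
  pops <- attr(variants, "populations")
  consequence <- suppressWarnings(
    parse_consequence(variants$hgvs_c, variants$hgvs_p))
  vapply(seq_len(nrow(variants)), function(i) {
    manual <- parse_evidence(variants$evidence[[i]])
    ev <- if (auto) {
      popmax <- if (length(pops))
        max(unlist(variants[i, pops, drop = FALSE]), 0) else 0
      assign_computational_evidence(
        consequence[[i]], popmax, variants$hgvs_c[[i]],
        revel = variants$revel[[i]],
        spliceai_max_delta = variants$spliceai_max_delta[[i]],
        manual = manual, thresholds = thresholds)
    } else manual
    combine_evidence(ev)
  }, "")
}

#' Flag disease alleles under a classification scheme
#'
#' Marks each record as a disease allele under one of the three schemes the
#' analysis supports: `acmg` (five-tier classification in pathogenic /
#' likely pathogenic), `clinvar` (ClinVar assertion PV or LPV), or `hgmd`
#' (HGMD disease-causing mutation, DM).
#'
#' @param variants A QC-filtered `variant_tbl`.
#' @param scheme One of `"acmg"`, `"clinvar"`, `"hgmd"`.
#' @param thresholds A [threshold_config()] (used by the `acmg` scheme).
#' @return Logical vector aligned with the input rows.
#' @export
disease_allele_mask <- function(variants, scheme = c("acmg", "clinvar", "hgmd"),
                                thresholds = threshold_config()) {
  stopifnot(inherits(variants, "variant_tbl"))
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e)
                       stop("unknown scheme: ", scheme[[1L]], call. = FALSE))
  switch(scheme,
         acmg = classify_variants(variants, thresholds) %in%
           c("pathogenic", "likely_pathogenic"),
         clinvar = variants$clinvar_class %in% c("PV", "LPV"),
         hgmd = variants$hgmd_class == "DM")
}
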