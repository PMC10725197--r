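#' Summarise the disease-allele spectrum by consequence class
#'
#' Counts variants and reconstructed alleles per consequence class for the
#' masked (disease-allele) subset of a variant table, in one population.
#'
#' @param variants A `variant_tbl`.
#' @param mask Logical disease-allele mask aligned with `variants`
#'   (see [disease_allele_mask()]); defaults to all records.
#' @param population Population label (one of `attr(variants, "populations")`).
#' @param n_individuals Cohort sample size of that population.
#' @return An object of class `spectrum_summary`: data frame with one row
#'   per consequence class (`consequence`, `variant_count`, `allele_count`;
#'   only classes with at least one variant kept), plus `total_variants`
#'   and `total_alleles` attributes. Variants with a reconstructed count of
#'   zero in the chosen population are not counted as present there.
#' @export
consequence_spectrum <- function(variants, mask = rep(TRUE, nrow(variants)),
                                 population, n_individuals) {
  stopifnot(inherits(variants, "variant_tbl"),
            length(mask) == nrow(variants))
  sub <- variants[mask, , drop = FALSE]
  counts <- if (nrow(sub)) population_allele_counts(sub, population, n_individuals)
            else integer()
  present <- counts > 0L
  cls <- if (nrow(sub)) suppressWarnings(
    parse_consequence(sub$hgvs_c, sub$hgvs_p)) else
    factor(character(), levels = consequence_levels())
  per <- data.frame(
    consequence = consequence_levels(),
    variant_count = as.integer(tapply(present, cls, sum, default = 0L)[consequence_levels()]),
    allele_count = as.integer(tapply(counts, cls, sum, default = 0L)[consequence_levels()]),
    stringsAsFactors = FALSE
  )
  per$variant_count[is.na(per$variant_count)] <- 0L
  per$allele_count[is.na(per$allele_count)] <- 0L
  per <- per[per$variant_count > 0L, , drop = FALSE]
  rownames(per) <- NULL
  structure(per,
            total_variants = sum(per$variant_count),
            total_alleles = sum(per$allele_count),
            population = population,
            class = c("spectrum_summary", "data.frame"))
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Variant spectrum (%s): %d variants, %d alleles\n",
              attr(x, "population"),
              attr(x, "total_variants"), attr(x, "total_alleles")))
  print(as.data.frame(x))
  invisible(x)
}

#' Rank disease alleles by recurrence
#'
#' Orders masked variants by reconstructed allele count (descending) in one
#' population; ties are broken by ascending `hgvs_c` lexicographic order so
#' reports are deterministic. Variants absent from the population (count 0)
#' are dropped.
#'
#' @inheritParams consequence_spectrum
#' @return Data frame with columns `hgvs_c`, `hgvs_p`, `allele_count`.
#' @export
rank_disease_alleles <- function(variants, mask = rep(TRUE, nrow(variants)),
                                 population, n_individuals) {
  stopifnot(inherits(variants, "variant_tbl"),
            length(mask) == nrow(variants))
  sub <- variants[mask, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(hgvs_c = character(), hgvs_p = character(),
                      allele_count = integer(), stringsAsFactors = FALSE))
  counts <- population_allele_counts(sub, population, n_individuals)
  out <- data.frame(hgvs_c = sub$hgvs_c, hgvs_p = sub$hgvs_p,
                    allele_count = counts, stringsAsFactors = FALSE)
  out <- out[out$allele_count > 0L, , drop = FALSE]
  out <- out[order(-out$allele_count, out$hgvs_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants exclusive to a focal population
#'
#' Returns the masked variants present (reconstructed allele count > 0) in
#' the focal population and absent from every population in `others`.
#' Presence uses reconstructed integer counts, not raw float frequencies,
#' so float rounding cannot create phantom sharing.
#'
#' @inheritParams consequence_spectrum
#' @param focal Focal population label.
#' @param others Character vector of population labels to exclude against
#'   (may be empty, in which case the exclusion is vacuous).
#' @param registry Named vector of cohort sizes (label -> `n_individuals`)
#'   covering `focal` and `others`.
#' @return Data frame with `hgvs_c`, `hgvs_p` and the focal allele count.
#' @export
population_exclusivity <- function(variants, mask = rep(TRUE, nrow(variants)),
                                   focal, others, registry) {
  stopifnot(inherits(variants, "variant_tbl"))
  if (focal %in% others)
    stop("focal population cannot be among the excluded populations",
         call. = FALSE)
  labels <- c(focal, others)
  if (!all(labels %in% names(registry)))
    stop("registry is missing cohort size(s) for: ",
         paste(setdiff(labels, names(registry)), collapse = ", "),
         call. = FALSE)
  sub <- variants[mask, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(hgvs_c = character(), hgvs_p = character(),
                      allele_count = integer(), stringsAsFactors = FALSE))
  focal_counts <- population_allele_counts(sub, focal, registry[[focal]])
  keep <- focal_counts > 0L
  for (lab in others) {
    keep <- keep &
      population_allele_counts(sub, lab, registry[[lab]]) == 0L
  }
  out <- data.frame(hgvs_c = sub$hgvs_c[keep], hgvs_p = sub$hgvs_p[keep],
                    allele_count = focal_counts[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
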