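#' Simulation settings for synthetic cohorts and variant tables
#'
#' @param true_q True disease-allele frequency, in `[0, 0.5]`.
#' @param n_individuals Diploid cohort size.
#' @param n_variants Number of variants for [simulate_variant_table()].
#' @param population_labels Populations across which variant alleles are
#'   spread.
#' @param evidence_profile_mix Named numeric vector of profile weights
#'   (must sum to 1); names must be profiles of [evidence_profiles()].
#' @param seed Integer seed; every synthetic artifact is reproducible for a
#'   fixed seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(true_q = 0.002, n_individuals = 10000,
                              n_variants = 50,
                              population_labels = c("popA", "popB"),
                              evidence_profile_mix = c(null_pm2 = 0.5,
                                                       missense_strong = 0.3,
                                                       benign = 0.2),
                              seed = 1L) {
  if (is.na(true_q) || true_q < 0 || true_q > 0.5)
    stop("true_q must lie in [0, 0.5]", call. = FALSE)
  if (n_individuals <= 0) stop("n_individuals must be positive", call. = FALSE)
  if (abs(sum(evidence_profile_mix) - 1) > 1e-8)
    stop("evidence_profile_mix weights must sum to 1", call. = FALSE)
  unknown <- setdiff(names(evidence_profile_mix), names(evidence_profiles()))
  if (length(unknown))
    stop("unknown evidence profile(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(true_q = true_q, n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 population_labels = population_labels,
                 evidence_profile_mix = evidence_profile_mix,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Named evidence profiles for synthetic variants
#'
#' Each profile fixes the evidence codes a synthetic variant carries, hence
#' (deterministically, via [combine_evidence()]) its intended
#' classification. `null_pm2` emulates an absent null variant (PVS1 + PM2,
#' likely pathogenic); `null_strong` a null variant with a matching
#' previously reported change (pathogenic); `missense_strong` a rare
#' missense with strong functional support (likely pathogenic);
#' `missense_vus` a rare missense with no further evidence; `benign` a
#' common variant (BA1).
#'
#' @return Named list: profile -> list(`codes`, `consequence`).
#' @export
evidence_profiles <- function() {
  list(
    null_pm2 = list(codes = c("PVS1", "PM2"), consequence = "nonsense"),
    null_strong = list(codes = c("PVS1", "PS1"), consequence = "frameshift"),
    missense_strong = list(codes = c("PS3", "PM2"), consequence = "missense"),
    missense_vus = list(codes = c("PM2"), consequence = "missense"),
    benign = list(codes = c("BA1"), consequence = "missense")
  )
}

#' Draw one Hardy-Weinberg cohort
#'
#' Samples `N` diploid genotypes with probabilities `(p^2, 2pq, q^2)` for
#' the (reference homozygote, heterozygote, disease homozygote) states and
#' returns the resulting disease-allele count (`het + 2 * hom`). A
#' homozygote carries two alleles but is one individual; the genotype
#' counts are returned so either carrier convention can be computed.
#'
#' @param true_q Disease allele frequency in `[0, 0.5]`.
#' @param n_individuals Cohort size `N`.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `disease_allele_count`, `genotype_counts` (named
#'   vector: `ref_hom`, `het`, `alt_hom`) and `carrier_count`
#'   (heterozygotes only).
#' @export
simulate_cohort <- function(true_q, n_individuals, seed = NULL) {
  if (is.na(true_q) || true_q < 0 || true_q > 0.5)
    stop("true_q must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - true_q
  g <- stats::rmultinom(1L, n_individuals, c(p^2, 2 * p * true_q, true_q^2))[, 1L]
  names(g) <- c("ref_hom", "het", "alt_hom")
  list(disease_allele_count = unname(g[["het"]] + 2L * g[["alt_hom"]]),
       genotype_counts = g,
       carrier_count = unname(g[["het"]]))
}

#' Generate a synthetic variant table with known ground truth
#'
#' Emits a variant table in the dialect [read_variant_table()] reads, with
#' evidence codes drawn from the configured profiles and each variant's
#' alleles spread multinomially across the population labels. The paired
#' truth table records the profile, the intended five-tier classification
#' (computed from the profile's codes) and the true per-population allele
#' counts, so classifier and counting stages can be checked end to end.
#'
#' @param config A [simulation_config()].
#' @param mean_alleles Mean total allele count per variant (1 + Poisson).
#' @return List with `variants` (a `variant_tbl`), `truth` (data frame) and
#'   `registry` (named cohort sizes per label).
#' @export
simulate_variant_table <- function(config, mean_alleles = 2) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  profiles <- evidence_profiles()
  labs <- config$population_labels
  n <- config$n_variants
  registry <- stats::setNames(rep(config$n_individuals, length(labs)), labs)
  if (n == 0L) {
    schema <- variant_schema(populations = stats::setNames(labs, labs),
                             qc_flags = "qc_flags", evidence = "evidence")
    empty <- read_variant_table(
      paste(c("hgvs_c\thgvs_p", labs, "qc_flags\tevidence"), collapse = "\t"),
      schema)
    return(list(variants = empty,
                truth = data.frame(hgvs_c = character(), profile = character(),
                                   expected_class = character(),
                                   stringsAsFactors = FALSE),
                registry = registry))
  }
  prof_names <- sample(names(config$evidence_profile_mix), n, replace = TRUE,
                       prob = config$evidence_profile_mix)
  hgvs <- synthetic_hgvs(prof_names, profiles)
  totals <- 1L + stats::rpois(n, mean_alleles - 1)
  split <- vapply(totals, function(tot)
    stats::rmultinom(1L, tot, rep(1, length(labs)))[, 1L],
    integer(length(labs)))
  split <- matrix(split, nrow = length(labs))
  af <- split / (2 * config$n_individuals)

  df <- data.frame(hgvs_c = hgvs$hgvs_c, hgvs_p = hgvs$hgvs_p,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df$qc_flags <- replicate(n, character(), simplify = FALSE)
  df$revel <- NA_real_
  df$spliceai_max_delta <- NA_real_
  df$clinvar_class <- "absent"
  df$hgmd_class <- "absent"
  df$evidence <- unname(vapply(prof_names, function(p)
    paste(profiles[[p]]$codes, collapse = ";"), ""))
  for (j in seq_along(labs)) df[[labs[[j]]]] <- af[j, ]
  attr(df, "populations") <- labs
  class(df) <- c("variant_tbl", "data.frame")

  truth <- data.frame(
    hgvs_c = hgvs$hgvs_c,
    profile = prof_names,
    expected_class = unname(vapply(prof_names, function(p)
      combine_evidence(profiles[[p]]$codes), "")),
    stringsAsFactors = FALSE)
  for (j in seq_along(labs)) truth[[paste0("count_", labs[[j]])]] <- split[j, ]
  list(variants = df, truth = truth, registry = registry)
}

# Deterministic HGVS strings consistent with each profile's consequence.
synthetic_hgvs <- function(prof_names, profiles) {
  n <- length(prof_names)
  pos <- 3L * seq_len(n) + 1L
  cons <- vapply(prof_names, function(p) profiles[[p]]$consequence, "")
  hc <- sprintf("c.%dG>A", pos)
  hp <- sprintf("p.(Gly%dSer)", (pos + 2L) %/% 3L)
  hp[cons == "nonsense"] <- sprintf("p.(Trp%d*)", ((pos + 2L) %/% 3L)[cons == "nonsense"])
  hc[cons == "frameshift"] <- sprintf("c.%ddel", pos[cons == "frameshift"])
  hp[cons == "frameshift"] <- sprintf("p.(Val%dTrpfs*10)", ((pos + 2L) %/% 3L)[cons == "frameshift"])
  list(hgvs_c = hc, hgvs_p = hp)
}

#' Empirical coverage of the exact carrier-frequency interval
#'
#' Simulates Hardy-Weinberg cohorts at a known allele frequency and
#' measures how often the exact binomial confidence interval for the
#' carrier frequency contains the true value `2q(1-q)`. Because
#' Clopper-Pearson intervals are conservative, the empirical coverage
#' should meet or exceed the nominal level.
#'
#' @param true_q True disease-allele frequency.
#' @param n_individuals Cohort size per replicate.
#' @param replicates Number of simulated cohorts (>= 100).
#' @param level Nominal confidence level.
#' @param seed Integer seed.
#' @return Coverage proportion in `[0, 1]`.
#' @export
ci_coverage_experiment <- function(true_q, n_individuals, replicates = 2000,
                                   level = 0.95, seed = 1L) {
  if (replicates < 100) stop("use at least 100 replicates", call. = FALSE)
  set.seed(seed)
  p <- 1 - true_q
  g <- stats::rmultinom(replicates, n_individuals,
                        c(p^2, 2 * p * true_q, true_q^2))
  x <- g[2L, ] + 2L * g[3L, ]
  ci <- clopper_pearson(x, n_individuals, level)
  truth <- 2 * true_q * (1 - true_q)
  mean(ci$lower <= truth & truth <= ci$upper)
}
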