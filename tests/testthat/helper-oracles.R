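# Independent oracles and small builders used across the suite.

# Toy variant table built from inline text.
toy_variants <- function(lines, populations = c(popA = "af_popA")) {
  schema <- variant_schema(populations = populations,
                           qc_flags = "qc", evidence = "evidence",
                           revel = "revel", spliceai = "spliceai",
                           clinvar = "clinvar", hgmd = "hgmd")
  read_variant_table(lines, schema)
}

# Clopper-Pearson oracle by bisection on the binomial CDF, independent of
# the Beta-quantile route: the lower bound solves P(X >= x | p) = alpha/2,
# the upper bound solves P(X <= x | p) = alpha/2.
cp_bisect <- function(x, n, level = 0.95, iter = 80L) {
  alpha <- (1 - level) / 2
  solve_mono <- function(f, target) {
    lo <- 0; hi <- 1
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    solve_mono(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE),
               alpha)
  upper <- if (x == n) 1 else
    solve_mono(function(p) 1 - stats::pbinom(x, n, p), 1 - alpha)
  c(lower = lower, upper = upper)
}

# ACMG/AMP combining-rule oracle: literal transcription of the guideline
# clauses as boolean conditions, with its own code catalogue. Conflicting
# sides (any pathogenic-side code together with any benign-side code)
# classify as uncertain significance.
oracle_combine <- function(codes) {
  side_of <- function(code) if (grepl("^(PVS|PS|PM|PP)", code)) "P" else "B"
  strength_of <- function(code) {
    if (grepl("^PVS", code)) return("vs")
    if (grepl("^PS", code)) return("s")
    if (grepl("^PM", code)) return("m")
    if (grepl("^PP", code)) return("p")
    if (grepl("^BA", code)) return("sa")
    if (grepl("^BS", code)) return("s")
    "p"
  }
  if (length(codes) == 0L) return("uncertain_significance")
  sides <- vapply(codes, side_of, "")
  if (length(unique(sides)) > 1L) return("uncertain_significance")
  k <- table(factor(vapply(codes, strength_of, ""),
                    levels = c("sa", "vs", "s", "m", "p")))
  sa <- k[["sa"]]; vs <- k[["vs"]]; s <- k[["s"]]; m <- k[["m"]]; p <- k[["p"]]
  if (all(sides == "P")) {
    if ((vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
        s >= 2 ||
        (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4))))
      return("pathogenic")
    if ((vs >= 1 && m >= 1) ||
        (s >= 1 && m >= 1) || (s >= 1 && p >= 2) ||
        m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4))
      return("likely_pathogenic")
    return("uncertain_significance")
  }
  if (sa >= 1 || s >= 2) return("benign")
  if ((s >= 1 && p >= 1) || p >= 2) return("likely_benign")
  "uncertain_significance"
}

man2b1_registry <- function() {
  cfg <- run_config(man2b1_config())
  cfg$cohort_registry
}
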