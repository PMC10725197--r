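Package: carrierfreq
Title: Carrier Frequency and Disease Incidence Estimation from Population
    Allele Databases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates autosomal recessive carrier frequencies and
    Hardy-Weinberg expected disease incidence from population allele
    databases such as gnomAD. Reads per-gene variant exports, applies
    database QC filters, parses HGVS nomenclature into consequence
    classes, classifies variants with a data-driven ACMG/AMP 2015 rule
    engine (with ClinVar and HGMD assertion schemes), reconstructs
    integer allele counts from printed frequencies, and turns
    disease-allele counts into carrier frequency estimates with exact
    Clopper-Pearson confidence intervals, incidence denominators,
    pooled multi-database estimates, variant-spectrum summaries and
    population-burden projections. Ships the MAN2B1 (alpha-mannosidosis)
    tables as worked fixtures, plus a Hardy-Weinberg cohort simulator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
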