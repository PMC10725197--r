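test_that("evidence sets carry default strengths, overrides, and reject bad codes", {
  ev <- evidence_set(c("PVS1", "PS1", "PM2", "PP3", "BA1", "BS1", "BP4"))
  expect_equal(ev$strength,
               c("very_strong", "strong", "moderate", "supporting",
                 "stand_alone", "strong", "supporting"))
  expect_equal(ev$side, c(rep("pathogenic", 4L), rep("benign", 3L)))
  # ClinGen-style strength modification
  ev2 <- evidence_set("PVS1:moderate")
  expect_equal(ev2$strength, "moderate")
  expect_error(evidence_set("PX9"), "unknown evidence code")
  expect_error(evidence_set(c("PM2", "PM2")), "duplicate")
  expect_error(evidence_set("PVS1:mild"), "strength")
})

test_that("computational evidence codes follow the three predicates", {
  th <- threshold_config()
  ev <- assign_computational_evidence("nonsense", popmax_af = 4e-6,
                                      hgvs_c = "c.12C>G", thresholds = th)
  expect_setequal(ev$code, c("PVS1", "PM2"))
  ev <- assign_computational_evidence("missense", popmax_af = 0,
                                      revel = 0.9, thresholds = th)
  expect_setequal(ev$code, c("PM2", "PP3"))
  ev <- assign_computational_evidence("missense", popmax_af = 0.02,
                                      revel = 0.1, thresholds = th)
  expect_setequal(ev$code, "BP4")
  # canonical splice yields PVS1, deep intronic does not
  ev <- assign_computational_evidence("splicing", 0, hgvs_c = "c.1830+1G>C")
  expect_true("PVS1" %in% ev$code)
  ev <- assign_computational_evidence("splicing", 0, hgvs_c = "c.1830+5G>C")
  expect_false("PVS1" %in% ev$code)
  # SpliceAI drives PP3 only for splice-relevant variants
  ev <- assign_computational_evidence("splicing", 0, hgvs_c = "c.1830+1G>C",
                                      spliceai_max_delta = 0.8)
  expect_true("PP3" %in% ev$code)
  # absent scores contribute no code
  ev <- assign_computational_evidence("missense", 0.5)
  expect_equal(nrow(ev), 0L)
  # manual codes merge with provenance, and win on collision
  ev <- assign_computational_evidence("nonsense", 0, hgvs_c = "c.12C>G",
                                      manual = evidence_set("PVS1:strong"))
  expect_equal(ev$strength[ev$code == "PVS1"], "strong")
  expect_equal(ev$provenance[ev$code == "PM2"], "auto")
})

test_that("combining rules reproduce the guideline examples", {
  expect_equal(combine_evidence(character()), "uncertain_significance")
  expect_equal(combine_evidence(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(combine_evidence(c("PVS1", "PS1")), "pathogenic")
  expect_equal(combine_evidence("BA1"), "benign")
  expect_equal(combine_evidence(c("PVS1", "BA1")), "uncertain_significance")
  expect_equal(combine_evidence(c("BS1", "BP1")), "likely_benign")
  expect_equal(combine_evidence(c("BP1", "BP2")), "likely_benign")
  expect_equal(combine_evidence(c("PM1", "PM2", "PM4")), "likely_pathogenic")
  expect_equal(combine_evidence(c("PS1", "PS2")), "pathogenic")
  expect_equal(combine_evidence("PVS1"), "uncertain_significance")
  # strength modification moves the classification
  expect_equal(combine_evidence(c("PVS1:moderate", "PM2")),
               "uncertain_significance")
})

test_that("combine_evidence matches a brute-force clause oracle over all small sets", {
  pool <- c("PVS1", "PS1", "PM1", "PM2", "PP1", "PP2", "BA1", "BS1", "BP1")
  for (k in 0:4) {
    sets <- utils::combn(pool, k, simplify = FALSE)
    for (s in sets)
      expect_equal(combine_evidence(s), oracle_combine(s),
                   label = paste(s, collapse = "+"))
  }
})

test_that("adding evidence never moves the classification across the scale the wrong way", {
  tiers <- c(benign = 1, likely_benign = 2, uncertain_significance = 3,
             likely_pathogenic = 4, pathogenic = 5)
  pool_p <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PP1", "PP2")
  pool_b <- c("BA1", "BS1", "BS2", "BP1", "BP2")
  set.seed(42)
  for (i in 1:200) {
    base <- c(sample(pool_p, sample(0:3, 1)), sample(pool_b, sample(0:2, 1)))
    before <- tiers[[combine_evidence(base)]]
    add_p <- setdiff(pool_p, base)
    if (length(add_p)) {
      after <- tiers[[combine_evidence(c(base, sample(add_p, 1)))]]
      # never toward the benign end: conflicting sets pin at VUS, pure
      # pathogenic sets can only hold or escalate
      if (any(base %in% pool_b)) expect_equal(after, 3)
      else expect_gte(after, before)
    }
    add_b <- setdiff(pool_b, base)
    if (length(add_b)) {
      after <- tiers[[combine_evidence(c(base, sample(add_b, 1)))]]
      if (any(base %in% pool_p)) expect_equal(after, 3)
      else expect_lte(after, before)
    }
  }
})

test_that("disease-allele masks follow the scheme definitions", {
  lines <- c("hgvs_c,hgvs_p,af_popA,clinvar,hgmd,evidence",
             "c.1A>G,p.(Met1Val),0.001,PV,DM,",
             "c.2T>C,p.(Met1Thr),0.001,VUS,other,",
             "c.3G>A,p.(Met1Ile),0.001,,,")
  v <- toy_variants(lines)
  expect_equal(disease_allele_mask(v, "clinvar"), c(TRUE, FALSE, FALSE))
  expect_equal(disease_allele_mask(v, "hgmd"), c(TRUE, FALSE, FALSE))
  expect_error(disease_allele_mask(v, "acmgx"), "scheme")
})

test_that("every packaged fixture variant classifies pathogenic or likely pathogenic", {
  v <- man2b1_variants()
  expect_true(all(disease_allele_mask(v, "acmg")))
  # with packaged evidence only (no computational codes) as well
  cls <- classify_variants(v, auto = FALSE)
  expect_true(all(cls %in% c("pathogenic", "likely_pathogenic")))
})
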