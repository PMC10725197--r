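test_that("the packaged 81-variant table reads with order and populations intact", {
  v <- man2b1_variants()
  expect_s3_class(v, "variant_tbl")
  expect_equal(nrow(v), 81L)
  expect_length(attr(v, "populations"), 9L)
  expect_equal(v$hgvs_c[[1L]], "c.12C>G")
  expect_equal(v$hgvs_c[[81L]], "c.2821-42_2872dup")
  expect_true(all(vapply(v$qc_flags, length, 0L) == 0L))
  expect_true(all(v$clinvar_class == "absent"))
})

test_that("header-only input yields an empty table and bad input errors name the row", {
  hdr <- "hgvs_c,hgvs_p,af_popA"
  schema <- variant_schema(populations = c(popA = "af_popA"))
  expect_equal(nrow(read_variant_table(hdr, schema)), 0L)

  lines <- c(hdr, "c.1A>G,p.(Met1Val),0.001", "c.2T>C,p.(Met1Thr),1.2",
             "c.3G>A,p.(Met1Ile),0")
  expect_error(read_variant_table(lines, schema), "row 2")
  expect_error(read_variant_table(c("hgvs_p,af_popA", "p.?,0"), schema),
               "hgvs_c")
  expect_error(read_variant_table("hgvs_c,hgvs_p", schema), "af_popA")
})

test_that("delimiter is auto-detected and a write/read roundtrip is lossless", {
  tsv <- c("hgvs_c\thgvs_p\taf_popA\tqc\tevidence",
           "c.1A>G\tp.(Met1Val)\t0.001\tAC0;RF\tPVS1;PM2")
  v <- toy_variants(tsv)
  expect_equal(v$qc_flags[[1L]], c("AC0", "RF"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  schema2 <- variant_schema(populations = c(popA = "popA"),
                            qc_flags = "qc_flags", evidence = "evidence")
  v2 <- read_variant_table(path, schema2)
  expect_equal(v2$hgvs_c, v$hgvs_c)
  expect_equal(v2$qc_flags, v$qc_flags)
  expect_equal(v2$popA, v$popA)
})

test_that("QC filtering removes flagged records, is idempotent and logs counts", {
  lines <- c("hgvs_c,hgvs_p,af_popA,qc",
             "c.1A>G,p.(Met1Val),0.001,",
             "c.2T>C,p.(Met1Thr),0.001,AC0",
             "c.3G>A,p.(Met1Ile),0.001,RF")
  v <- toy_variants(lines)
  expect_message(kept <- apply_qc_filters(v), "2 of 3")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$hgvs_c, "c.1A>G")
  # idempotent, never grows
  expect_message(again <- apply_qc_filters(kept))
  expect_equal(nrow(again), 1L)
  # empty exclusion set keeps everything
  expect_message(all_kept <- apply_qc_filters(v, character()))
  expect_equal(nrow(all_kept), 3L)
  # unknown flags are ignored but logged
  lines2 <- c("hgvs_c,hgvs_p,af_popA,qc", "c.1A>G,p.(Met1Val),0.001,oddflag")
  expect_message(apply_qc_filters(toy_variants(lines2)), "oddflag")
  # the packaged fixture carries no flags
  expect_message(vv <- apply_qc_filters(man2b1_variants()), "0 of 81")
  expect_equal(nrow(vv), 81L)
})

test_that("HGVS consequence parsing follows the documented precedence", {
  cases <- list(
    list("c.2248C>T", "p.(Arg750Trp)", "missense"),
    list("c.1830 + 1G>C", "p.?", "splicing"),
    list("c.2355G>A", "p.(Thr785 = )", "synonymous"),
    list("c.241del", "p.(Val81Trpfs*76)", "frameshift"),
    list("c.12C>G", "p.(Tyr4*)", "nonsense"),
    # frameshift outranks splicing-looking coding changes
    list("c.2821-42_2872dup", "p.(Ala958Glyfs*?)", "frameshift"),
    list("c.2437-2A>G", "p.?", "splicing")
  )
  for (cs in cases)
    expect_equal(as.character(parse_consequence(cs[[1]], cs[[2]])), cs[[3]],
                 label = cs[[1]])
  expect_warning(res <- parse_consequence("c.1A>G", "p.?"), "other")
  expect_equal(as.character(res), "other")
  expect_error(parse_consequence("", "p.?"), "non-empty")
})

test_that("the fixture partitions into the published five consequence classes", {
  v <- man2b1_variants()
  cls <- parse_consequence(v$hgvs_c, v$hgvs_p)
  expect_equal(as.vector(table(cls)[c("missense", "nonsense", "frameshift",
                                      "splicing", "synonymous", "other")]),
               c(30L, 22L, 16L, 12L, 1L, 0L))
  expect_equal(sum(table(cls)), 81L)
})

test_that("allele counts are recovered from printed frequencies", {
  expect_equal(reconstruct_allele_count(2.35e-4, 125748), 59L)
  expect_equal(reconstruct_allele_count(0, 125748), 0L)
  expect_equal(reconstruct_allele_count(9.15e-5, 125748), 23L)
  expect_equal(reconstruct_allele_count(3.98e-6, 125748), 1L)
  expect_error(reconstruct_allele_count(-0.1, 100), "\\[0, 1\\]")
  expect_error(reconstruct_allele_count(0.5, 100, allele_number = -2),
               "positive")
  # printed 3-sig-fig AFs never round across an integer boundary here
  v <- man2b1_variants()
  for (pop in attr(v, "populations")) {
    n <- man2b1_registry()[[pop]]
    counts <- reconstruct_allele_count(v[[pop]], n)
    expect_true(all(abs(counts - v[[pop]] * 2 * n) <= 0.5), label = pop)
  }
})
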