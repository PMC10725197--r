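# MAN2B1 / alpha-mannosidosis carrier-frequency analysis configuration.
gene: MAN2B1
transcript: NM_000528.4

variant_table: man2b1_gnomad_variants.tsv
cohort_counts: man2b1_cohort_counts.tsv

schema:
  hgvs_c: hgvs_c
  hgvs_p: hgvs_p
  qc_flags: qc_filters
  evidence: evidence
  populations:
    Total: af_total
    East Asian: af_east_asian
    African: af_african
    Latino: af_latino
    Ashkenazi Jewish: af_ashkenazi_jewish
    European (Finnish): af_european_finnish
    European (non-Finnish): af_european_non_finnish
    South Asian: af_south_asian
    Other: af_other

# gnomAD v2.1.1 exome sample sizes per population
cohort_registry:
  Total: 125748
  East Asian: 9197
  African: 8128
  Latino: 17296
  Ashkenazi Jewish: 5040
  European (Finnish): 10824
  European (non-Finnish): 56885
  South Asian: 15308
  Other: 3070

excluded_qc_flags: [InbreedingCoeff, AC0, RF]

# schemes computed from the variant table; clinvar/hgmd estimates come from
# the cohort_counts table (per-variant assertions are not part of this export)
schemes_from_variants: [acmg]

thresholds:
  revel_pp3_min: 0.75
  revel_bp4_max: 0.25
  spliceai_pp3_min: 0.2
  pm2_popmax_max: 1.0e-4

pooling:
  Korean (pooled):
    - Korean
    - Korean (KOVA)
    - Korean (KRGDB)

projection:
  cohort: Korean (pooled)
  population_size: 51700000
  annual_births: 260562
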