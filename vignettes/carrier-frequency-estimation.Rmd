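---
title: "Estimating carrier frequency and recessive disease incidence from population databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carrier frequency and recessive disease incidence from population databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierfreq)
```

## The model

For an autosomal recessive disorder in a randomly mating population,
Hardy–Weinberg equilibrium gives genotype proportions
$p^2 + 2pq + q^2 = 1$, where $q$ is the disease allele frequency and
$p = 1 - q$. Heterozygotes ($2pq$) are healthy carriers; homozygotes
($q^2$) are affected. A population sequencing database that reports the
allele frequency of each variant in a gene lets us estimate $q$ directly
from healthy individuals, without ascertaining patients:

* Let $x$ be the number of disease alleles observed among $N$ sequenced
  individuals ($2N$ chromosomes). Then $\hat q = x/2N$.
* The **carrier frequency** is reported as $x/N = 2\hat q$. The exact
  Hardy–Weinberg carrier proportion is $2\hat q(1-\hat q)$; for the
  allele frequencies this analysis deals in ($q < 0.01$) the difference
  is below reporting precision, and $x/N$ is the scale on which an exact
  binomial interval is natural. The package keeps both conventions
  available (the simulator reports heterozygote counts separately) so the
  approximation error is measurable rather than hidden.
* The **expected incidence** is $\hat q^2$, reported as a denominator
  $1/\hat q^2$ ("1 in ...").

Summing $x$ over variants treats every disease allele as borne by a
distinct carrier. At these frequencies the probability of a sampled
individual carrying two of the counted alleles is negligible, which is
also why compound heterozygosity does not perturb the count.

### Confidence intervals

All intervals are exact Clopper–Pearson binomial intervals computed from
Beta quantiles: for $x$ successes in $n$ trials at level $1-\alpha$,

$$\mathrm{lower} = B_{\alpha/2}(x,\, n-x+1), \qquad
  \mathrm{upper} = B_{1-\alpha/2}(x+1,\, n-x),$$

with the conventions lower $= 0$ at $x = 0$ and upper $= 1$ at $x = n$.
The exact interval was chosen over Wald/Wilson approximations because the
counts involved are tiny (often 0–4 alleles in thousands of individuals):
exact intervals remain valid and asymmetric there, e.g. one carrier among
5,040 individuals yields an upper bound of 0.11%, and zero carriers still
yield an informative upper bound (0.07% at $n = 5{,}040$). The price is
conservatism — empirical coverage exceeds the nominal 95% — which the test
suite measures by simulation rather than assumes.

The carrier-frequency interval is the binomial interval for $x$ out of
$N$. The incidence interval is derived on the **allele scale**: the
interval for $x$ out of $2N$ is squared bound-wise and inverted, giving a
denominator pair reported larger-first ("1/297,304–1/97,504"). Deriving
it on the allele scale and transforming (rather than intervaling $q^2$
directly) is what reproduces published incidence bounds to within 0.1%.
A zero-count cohort reports an undefined (`NA`) incidence denominator but
keeps the finite denominator implied by the upper allele-frequency bound.

## Deciding which alleles count

Three schemes are supported and can be compared side by side:

* **acmg** — a five-tier classification (pathogenic, likely pathogenic,
  uncertain, likely benign, benign) computed by a rule engine from
  ACMG/AMP 2015 evidence codes. The combining rules are *data*
  (`acmg_rule_table()`), one row per guideline clause, so alternative
  guideline versions can be swapped in without touching code. Evidence
  sets mixing pathogenic-side and benign-side codes classify as uncertain
  significance — the guideline's default for conflicting evidence; no
  arbitration score is attempted. Strength modification
  (e.g. `"PVS1:moderate"`) is supported on input but never auto-assigned.
* **clinvar** — assertion column equals PV or LPV.
* **hgmd** — assertion column equals DM.

The engine auto-assigns only the computational codes that follow
mechanically from the record: PVS1 for null variants (nonsense,
frameshift, canonical ±1/±2 splice), PM2 for rarity (maximum
per-population allele frequency below `pm2_popmax_max`), PP3/BP4 from
REVEL and SpliceAI scores. Literature, segregation and functional codes
must be supplied as input (an `evidence` column). Score thresholds
default to community-typical values (REVEL ≥ 0.75 for PP3, ≤ 0.25 for
BP4, SpliceAI Δ ≥ 0.2, popmax < 10⁻⁴ for PM2) and are configurable via
`threshold_config()`; the packaged MAN2B1 analysis does not depend on
them because its variant table ships evidence codes.

### HGVS consequence parsing

Consequence classes are derived from the HGVS strings by precedence:
frameshift (`fs` in the protein change) → nonsense (single residue to a
stop) → synonymous (`=`) → splicing (`p.?` with an intronic offset in the
coding change) → missense. Frameshift outranking splicing matters for
duplications whose coordinates span an intron boundary but whose product
is a frameshift (e.g. `c.2821-42_2872dup p.(Ala958Glyfs*?)`). Whitespace
inside printed HGVS (a typographic artifact of published tables, as in
`c.1830 + 1G>C`) is stripped before parsing. Unparseable descriptions
fall through to `other` with a warning — never an error, so one odd row
cannot kill a run.

### Reconstructing counts from printed frequencies

Published tables print allele frequencies to ~3 significant figures; the
underlying integer count is recovered as `round(AF × 2N)` (half away from
zero), using the maximal allele number $2N$ because per-variant allele
numbers (which vary with coverage) are rarely printed. On the packaged
MAN2B1 table this recovers the published global total (284 alleles) and
every headline per-population count exactly; two populations (African,
non-Finnish European) come out 2 alleles higher than the published
per-population table, which is the expected footprint of unprinted
per-variant allele numbers. For the same reason incidence denominators
are compared at 0.5% relative tolerance rather than exactly.

## The packaged MAN2B1 analysis

The fixtures encode the alpha-mannosidosis (MAN2B1, NM_000528.4) analysis
of gnomAD v2.1.1:

* `man2b1_gnomad_variants.tsv` — 81 pathogenic / likely pathogenic
  variants with allele frequencies in nine populations. Because the
  per-variant evidence codes behind the published classifications are not
  part of the export, each variant carries *minimal evidence consistent
  with its published status* (PVS1;PM2 for null variants, PS1;PM2
  otherwise); this is a packaging convention, and the engine classifies
  every row P/LP from it.
* `man2b1_cohort_counts.tsv` — per-population disease-allele counts and
  cohort sizes under the three schemes, plus the Korean sub-cohorts:
  gnomAD Korean (0/1,909), KOVA (3/5,305) and KRGDB (1/1,722). The KOVA
  and KRGDB counts are back-derived from their published carrier
  frequencies and incidences (the per-variant Korean table is not
  public); the KRGDB incidence recomputes exactly from the back-derived
  count, the KOVA one to 0.004%.
* `man2b1_config.yaml` — the run configuration: schema, cohort registry,
  QC flags, the Korean pooling group, and the census projection
  parameters (South Korea 2021: 51.7 M population, 260,562 births).

```{r}
report <- run_pipeline(man2b1_config())
report
```

One prose claim in the source analysis conflicts with its own table: the
`c.565C>A p.(Pro189Thr)` variant is described in one place as European
and elsewhere (and in the per-variant table) as East Asian-specific. The
fixture follows the table, under which every East Asian disease allele is
absent from the Latino, Ashkenazi Jewish and South Asian cohorts — a
property the test suite asserts.

### Projection convention

Census projections (`project_burden()`) multiply the carrier frequency by
population size (reported to the nearest thousand) and annual births
(nearest unit), and divide births by the incidence denominator (two
decimals). `run_pipeline()` feeds the *reported* carrier frequency — the
2-decimal percent — into the projection, matching how such figures are
quoted downstream of a published table: 0.04% of 260,562 births gives 104
carrier newborns (the unrounded 4/8,936 would give 117).

## The simulator, and what passing tests show

`simulate_cohort()` draws $N$ diploid genotypes from
$(p^2,\,2pq,\,q^2)$ and reports allele, genotype and carrier counts.
`simulate_variant_table()` writes variant tables in the exact input
dialect, with evidence codes drawn from named profiles and each variant's
alleles spread multinomially across populations, paired with a truth
table of intended classifications and true counts. A single seed threads
through all draws; every artifact is reproducible.

The generator emulates what the estimator assumes: Hardy–Weinberg
genotype sampling at a fixed $q$, a fixed allele number $2N$ at every
site, and evidence that determines classification. It deliberately does
not model linkage between variants, sequencing error, per-site coverage
variation, or population substructure — so passing tests demonstrate the
statistical machinery is correct *given* the model, not that real
databases satisfy the model. The measured checks are:

* empirical 95% CI coverage over 2,000 simulated cohorts at
  $q = 0.002$, $N = 10{,}000$ (the design point of the packaged
  analysis's mid-size cohorts) is at least nominal;
* the mean of $\hat q$ over 1,000 cohorts is within 2 Monte-Carlo
  standard errors of the true $q$;
* recovered $\hat q$ lies within 3 binomial standard errors of $q$ for
  $q \in \{0.0005, 0.002, 0.01\}$ at $N = 10{,}000$;
* the rule engine agrees with a brute-force transcription of the
  guideline clauses over every evidence set of up to 4 codes drawn from a
  9-code pool (256 sets);
* the Beta-quantile interval agrees with bisection on the binomial CDF
  to $10^{-9}$ over a grid of $n \le 500$.

These problem sizes keep the default suite under a minute while leaving
the Monte-Carlo error small relative to the tolerances tested.

## Numerical and design notes

* Rounding of reconstructed counts is half-away-from-zero, not banker's:
  printed 3-significant-figure frequencies sit close enough to integer
  counts that the convention matters (e.g. $2.35\times10^{-4} \times
  251{,}496 = 59.1 \to 59$).
* Ranking of recurrent alleles breaks ties lexicographically on the
  coding HGVS so reports are byte-stable across runs.
* Presence of a variant in a population is decided on reconstructed
  integer counts ($> 0$), never on raw float frequency, avoiding
  float-epsilon phantom sharing.
* Pooling requires a single scheme across cohorts and distinct labels;
  equal-rate pooling preserves the frequency exactly.
* A saturated cohort ($x = 2N$) has $q = 1$ and incidence denominator 1;
  its carrier-count interval is computed at the $x = N$ boundary.
* Known limitations: structural variants are not handled (large
  deletions would be invisible to a SNV/indel export and bias carrier
  frequency downward); incidence is a genetic expectation, not an
  observed birth prevalence; zero-count subpopulations (e.g. gnomAD
  Korean alone) yield only an upper bound.
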