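---
title: "Multi-pipeline variant rescue: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pipeline variant rescue: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sequencing-based rare-variant studies call genotypes with a single
read-to-variant pipeline — one read aligner followed by joint genotyping of
all samples — and treat the result as "the" variant set. But different
aligners disagree in regions that are hard to map, and joint genotyping can
discard a true allele carried by one sample out of thousands because the
handful of supporting reads looks statistically insignificant at cohort
scale. Both effects grow with sample size, and both fall disproportionately
on rare variants, which are exactly what large cohorts are assembled to
find. `rescuevar` quantifies this: it compares call-sets from different
aligner × genotyping-strategy configurations, categorizes the variants that
the default pipeline misses but an alternative recovers ("rescued"
variants), and profiles every variant group with a battery of quality
metrics to ask whether the rescued calls look like noise or like real
biology.

Because the motivating cohort data (large Alzheimer's-disease exome sets)
is access-controlled, the package also ships a generative simulator that
reproduces the relevant statistical structure — a heavily rare-skewed
frequency spectrum, region-dependent aligner dropout, and
carrier-count-dependent joint-genotyping loss — so that every stage of the
analysis is exercised end to end on data whose ground truth is known.

## Variant identity and inclusion rules

All cross-pipeline matching uses the exact tuple (chromosome, 1-based
position, reference allele, alternate allele), rendered as the key
`"chrom:pos:ref:alt"`. There is no positional window and no allele
re-normalization: after restriction to bi-allelic SNVs on a common
reference, exact identity is the correct equivalence. Chromosome labels are
compared after stripping an optional `chr` prefix, since GRCh37 resources
mix the two dialects.

The inclusion filter retains records that

* carry the literal FILTER value `PASS` (anything else, including `"."`,
  fails — the upstream recalibration's verdict is consumed as given);
* name exactly one alternate allele, with single-base REF and ALT
  (multi-allelic sites are dropped, not split: the analysis is defined over
  bi-allelic SNVs and splitting would manufacture records the upstream
  pipelines never emitted);
* when a minimum call rate is configured, have a called genotype in at
  least that fraction of the roster. The boundary is inclusive ("at least
  90%" keeps a record at exactly 0.90). A genotype is called iff both
  alleles are non-missing; half-calls count as missing.

The call-rate criterion is applied per call-set, before comparison, and only
to joint-genotyping call-sets: under single-sample genotyping a same-as-
reference call cannot be distinguished from no call, so a call rate is not
well defined and the criterion is skipped (`min_call_rate = NULL`).

## The comparison and the 2×2 rescue

`compare_callsets()` reduces two call-sets to unique/shared/union counts and
percentages of the union; genotypes are deliberately ignored (the analysis
compares variant *sites*, not genotype concordance). `rescue_sets()` extends
this to the 2×2 of {default aligner, alternate aligner} × {joint,
single-sample}: every key in the union gets presence flags for each
provided call-set and exactly one category —

* `shared_all` / `default_only` / `other` for keys the default pipeline
  found;
* `rescued_by_aligner`: absent from default, present in the alternate
  aligner's joint call-set but in no single-sample set;
* `rescued_by_genotyping`: absent from both joint call-sets, present in a
  single-sample set;
* `rescued_by_both`: absent from default, present in both the alternate
  aligner's set and a single-sample set.

The three rescue categories are disjoint by construction (the "both"
category is carved out of the other two), so the six categories partition
the union; the raw presence flags are reported alongside so users can
re-cut the categories differently.

`subsample_experiment()` reproduces the size-dependence design: for each
sample size it draws five subsets of the pool uniformly without
replacement, invokes both pipeline providers on each subset, and reports
the per-size mean and SD of the shared/unique percentages. Seeding is
two-level: the subset for (size, replicate) derives deterministically from
the design seed, so any cell can be re-run alone; the provider seed derives
from the subset *content*, so identical subsets — e.g. every replicate at
the full pool size — produce identical call-sets and an SD of exactly zero.

## The quality-metric battery

For any variant group (e.g. "unique to the alternate aligner"),
`build_quality_profile()` assembles:

* **BAP** (B allele proportion): per carrier genotype call,
  `alt_reads / (ref_reads + alt_reads)` from the AD field, pooled across
  the group (not averaged per variant first — the pooled distribution is
  what shows the diploid 0.5/1.0 modes). Carrier calls without usable AD
  are skipped and counted.
* **BAF** (B allele frequency): per variant, alternate-allele count over
  2 × called genotypes; missing genotypes leave the denominator. The
  histogram's first bin is an explicit "≤ 0.5%" class, the working
  definition of *very rare* here; bins are right-closed so exactly 0.5%
  falls in it.
* **Carrier counts** replace BAF for single-sample call-sets, binned as
  singleton / 2–4 / ≥ 5 carriers.
* **GQ and DP** histograms over called genotypes (GQ in width-5 bins on
  [0, 100], DP log2-spaced).
* **Flanking GC**: fraction of G/C among up to `window` bases on *each*
  side of the position (default 100 per side, 200 total; the wording "100
  bases flanking" is ambiguous between per-side and total, so the window is
  a parameter), truncated at chromosome ends, `N` bases excluded from both
  numerator and denominator.
* **Region assignment**: each variant is placed in exactly one of
  LCR / SDR / other using half-open BED semantics; LCR takes precedence
  when region sets overlap (the categories are reported as disjoint and no
  precedence is stated in the field's convention, so one had to be chosen
  and documented).
* **Ti/Tv**: transitions are A↔G and C↔T; the ratio is flagged undefined
  (counts still returned) when there are no transversions.
* **Functional tiers**: Tier 1 = start/stop disruption or splicing, Tier 2
  = non-synonymous coding change, Tier 3 = everything else; the
  highest tier among a variant's consequence terms wins, unknown terms fall
  through to Tier 3 with a warning (or an error in strict mode). The
  term-to-tier table is explicit and user-extensible; which exact strings
  denote "splicing events" is an assumption recorded in
  `tier_vocabulary()`.
* **Known/novel**: known = exact-key membership in any source of the
  known-variant index (no rsID or positional fuzziness); the novel
  high-CADD fraction uses an inclusive threshold (CADD PHRED ≥ 20, the top
  1% most deleterious substitutions).

Every histogram conserves its input count (bin counts sum to the number of
contributing values; out-of-range values are clamped into the end bins).

## The sample-QC cascade

`apply_sample_qc()` evaluates, per sample: coverage (≥ 10× over ≥ 90% of
target *and* ≥ 40× over ≥ 30%), call rate ≥ 95%, Ti/Tv ≥ 2.8, contamination
(fail iff FREEMIX strictly exceeds 0.02 — the one strict inequality, as
worded), the sex check (reported males fail when the X-chromosome
inbreeding F < 0.7, females when F > 0.3), APOE genotype concordance, and
the population-level relatedness/ancestry/batch flags. A sample can fail
several criteria and is counted under each; the retained set is the samples
failing none. Missing metrics make a criterion indeterminate: by default
the sample is excluded with reason `missing_metric` (configurable), except
that an unknown reported sex retains the sample on the sex criterion —
removing a sample because its sex was not recorded would be overreach.

The F statistic itself (`inbreeding_f()`) is the method-of-moments estimate
F = (O_hom − E_hom) / (m − E_hom) with E_hom = Σ (1 − 2p(1−p)). The
estimators behind the inputs (contamination, kinship, ancestry) are
upstream tools; this package consumes their outputs.

## The generative simulator

`cohort_model()` + `generate_truth_cohort()` draw a ground-truth cohort:

* **Spectrum**: a proportion `prop_singleton` (default 0.5) of variants are
  *singleton-class* — placed in exactly one heterozygous carrier, the
  private variants that joint genotyping is most likely to lose. The
  remaining variants draw a MAF from Beta(1.5, 8) (mean ≈ 0.16), truncated
  to [1/(2n), 0.5], and genotypes per sample under Hardy–Weinberg. The
  point mass carries the rare skew; the Beta tail is deliberately a
  *common*, reliably detectable mass, which is what makes the overlap
  between two pipelines start high at small sample sizes and fall as
  growing subsets pull in ever more singletons — the size-dependent
  divergence the analysis is about. A spectrum whose tail is itself
  near-singleton (e.g. Beta(0.25, 10)) leaves every subset carrier count
  tiny, so the pipelines already disagree at n = 50 and the decline
  flattens; it remains available as a parameter.
* **Regions**: a synthetic reference is tiled into 2 kb blocks assigned to
  LCR/SDR/other at configurable base fractions (defaults 1%/5%), with
  per-class GC composition (0.30/0.45/0.45 — low-complexity sequence is
  AT-rich); variant positions are then sampled to hit target per-class
  variant fractions (defaults 0.5%/4%/95.5%, the order of magnitude seen in
  exome call-sets).
* **Alleles** follow a transition:transversion ratio of 3 (exome-typical).

`pipeline_model()` + `emulate_pipeline()` turn truth into a call-set:

* **Aligner** differences are region-class detection sensitivities — the
  defaults give one aligner 0.90 and the other 0.97 inside segmental
  duplications, with near-1 sensitivity elsewhere, reflecting that aligners
  differ mainly where mapping is hard. Alignment itself is not simulated.
* **Joint genotyping** drops a detected variant with probability
  q_k = q₁ · d^(k−1) where k is the subset carrier count (defaults q₁ =
  0.3, d = 0.5). This is the minimal model of cross-sample evidence
  deeming a rare allele's reads insignificant: maximal for singletons,
  vanishing for common variants. No quantitative dropout rates exist to
  calibrate against, so the defaults are illustrative and every acceptance
  property about them is either parameter-recovery (the pipeline estimates
  q₁ back from the data) or directional (the trend, not its magnitude).
* **Single-sample genotyping** instead retains each carrier's site-call
  independently (default per-call dropout 2%) and emits the variant if any
  carrier survives; non-carriers become no-calls, reproducing the
  no-call/hom-ref ambiguity that makes call rates and BAF undefined in this
  mode.
* **Per-call noise**: DP ~ NegBin(μ = 60, size = 8) (exome-like depth),
  AD for a heterozygote ~ Binomial(DP, 0.5) (hom-alt 0.99, hom-ref 0.005
  error reads), GQ = min(99, 3·DP), and a 1% chance of a non-PASS FILTER
  label. Simple, documented, replaceable.

All randomness flows from one master seed through named sub-streams
(reference, cohort, per-pipeline, per-subset), so bundles regenerate
byte-identically.

**What the simulator does not emulate**: linkage disequilibrium, indels and
multi-allelic sites, read-level artifacts (strand bias, mapping quality),
batch effects, or any correlation between region class and allele
frequency. Passing tests therefore demonstrate that the *analysis
machinery* is correct and that the *qualitative* mechanisms suffice to
produce the reported structure — not that real cohorts will show these
exact percentages.

## Numerical and degenerate-input choices

* Percentages are exact ratios; the only rounding is the curated-table
  audit's whole-percent figure, rounded half-up.
* An empty union is an error in `compare_callsets()` (percentages would be
  undefined), as are empty variant groups in the metric functions and zero
  called genotypes in `baf()`.
* A Ti/Tv ratio with zero transversions is flagged undefined rather than
  returned as infinity.
* Histogram bins are right-closed with the lowest edge included, so
  threshold values land in the "≤" bin; values outside the edges are
  clamped into the end bins to preserve count conservation.
* VCF writing is deterministic (coordinate-sorted records, fixed FORMAT
  `GT:GQ:DP:AD`, `.` for missing), and the pipeline's JSON summary embeds
  the seed and a hash of the configuration (excluding the output
  directory), so identical inputs give byte-identical outputs.

## Problem sizes

The shipped tests and the acceptance script run the simulator at desk
scale, chosen as the smallest sizes at which the stochastic properties are
sharp: cohorts of 500–600 samples × 4000–5000 variants for the
parameter-recovery and trend experiments (20 seeded replicates for
recovery; subsample sizes 50–500 with 5 replicates each), and
50–200-sample bundles for the end-to-end pipeline checks. The cohort-scale
counts reported for real 2000–10,000-exome studies are not reproducible at
these sizes and are treated as trend-level targets only.

## Known limitations

* Genotype-level concordance between pipelines is out of scope; matching
  is by site.
* No statistical tests compare quality profiles between groups — the
  profiles are descriptive, as in the motivating analyses.
* Only plain or gzip text I/O (no bgzip/tabix); no structural variants; no
  phasing semantics (`|` is treated like `/`).
* The curated-variant audit operates on a transcribed table keyed by
  (gene, protein change); it does not re-derive protein consequences.
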