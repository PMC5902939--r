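# rescuevar

Variant calling from sequencing data is usually done with one pipeline —
one read aligner, followed by joint genotyping of all samples — and the
resulting call-set is treated as complete. It isn't: different aligners
disagree in hard-to-map regions (segmental duplications especially), and
joint genotyping tends to drop very rare alleles because a single carrier's
supporting reads look insignificant against thousands of samples. Both
losses grow with cohort size and fall mostly on rare variants, the very
targets of large exome studies of complex disease.

`rescuevar` is an R package for quantifying and characterizing those
losses. It is written for analysts of large exome/genome cohorts who have
(or can emulate) call-sets from more than one pipeline configuration and
want to know how many variants a single pipeline misses, which ones can be
*rescued* by an alternate aligner and/or single-sample genotyping, and
whether the rescued calls look like genuine variation.

## What it computes

* **Call-set comparison** by exact variant identity
  (chrom, pos, ref, alt): unique/shared/union counts and percentages
  (`compare_callsets()`), and the repeated-subsampling experiment that
  traces how the overlap between two pipelines shrinks as the sample size
  grows (`subsample_experiment()`: each size drawn 5 times, mean ± SD).
* **The 2×2 rescue**: every variant in the union of up to four call-sets
  (default/alternate aligner × joint/single-sample genotyping) is
  categorized as `shared_all`, `default_only`, `rescued_by_aligner`,
  `rescued_by_genotyping`, or `rescued_by_both` (`rescue_sets()`).
* **Variant inclusion filtering** as used in such comparisons: VQSR-PASS
  bi-allelic SNVs, optional ≥ 90% call-rate threshold
  (`filter_pass_biallelic_snv()`).
* **A quality-metric battery** per variant group
  (`build_quality_profile()`): pooled carrier allele balance
  (BAP = alt reads / total reads), the B allele frequency spectrum with an
  explicit "≤ 0.5%" rare class (or carrier-count spectrum where BAF is
  undefined), GQ/DP histograms, flanking GC content, chromosome
  distribution, overlap with low-complexity (LCR) and
  segmental-duplication (SDR) regions, Ti/Tv ratio, functional tier
  composition (Tier 1 start/stop/splice, Tier 2 non-synonymous, Tier 3
  other), and the known/novel split with the CADD ≥ 20 novel-deleterious
  fraction.
* **Sample QC**: the exome sample-level cascade — coverage, call rate,
  Ti/Tv ≥ 2.8, FREEMIX contamination > 0.02, the X-inbreeding sex check
  (F = (O_hom − E_hom)/(m − E_hom); males fail < 0.7, females fail > 0.3),
  APOE concordance and population-level flags (`apply_sample_qc()`,
  `inbreeding_f()`).
* **A curated-variant audit**: the packaged table of 13 previously
  published pathogenic/protective coding mutations in the early-onset
  Alzheimer's genes APP, PSEN1 and PSEN2, with how many the default
  pipeline detected (`audit_curated_table()`).
* **A generative simulator** (`cohort_model()`, `pipeline_model()`,
  `generate_study_bundle()`) producing truth cohorts and per-pipeline VCFs
  with a rare-skewed frequency spectrum, region-dependent aligner dropout
  and carrier-count-dependent joint-genotyping loss, so the whole analysis
  runs end to end without access-controlled data.

File formats go through standard tooling: VCF via `vcfR`, BED intervals via
`GenomicRanges`, FASTA via `Biostrings`; reports are TSV + JSON.

## Worked example

Simulate a study bundle (three pipeline configurations over one truth
cohort) and run the full comparison/rescue/profiling/QC pipeline:

```r
library(rescuevar)

cm <- cohort_model(n_samples = 200, n_variants = 2000, seed = 7)
pipelines <- list(
  pipeline_model("BWA-joint",
                 aligner_sensitivity = c(lcr = 0.95, sdr = 0.90, other = 0.998)),
  pipeline_model("Novo-joint",
                 aligner_sensitivity = c(lcr = 0.95, sdr = 0.97, other = 0.995)),
  pipeline_model("Novo-single", genotyping_mode = "single"))
cfg <- generate_study_bundle(cm, pipelines, "readme_bundle", seed = 7)
res <- run_pipeline(cfg)
print(res$comparison)
print(res$rescue)
print(res$profiles$unique_b)
```

which prints:

```
[BWA-joint] 1663 records read, 1646 retained after filtering
[Novo-joint] 1654 records read, 1640 retained after filtering
[Novo-single] 1972 records read, 1954 retained after filtering
ComparisonResult BWA-joint vs Novo-joint (union 1899)
  unique to BWA-joint: 259 (13.64%)
  unique to Novo-joint: 253 (13.32%)
  shared:        1387 (73.04%)
RescueResult: union 1996 keys, 350 (17.54%) absent from default
           shared_all          default_only                 other
                 1366                    10                   270
   rescued_by_aligner rescued_by_genotyping       rescued_by_both
                   11                    97                   242
QualityProfile 'Novo-joint-unique' (joint mode): 253 variants
  BAF <= 0.5%: 93.68%
  LCR 1.19%  SDR 4.35%  other 94.47%
```

Reading this: the two aligners agree on 73% of the union at this cohort
size; 17.5% of all pass-filter variants are invisible to the default
pipeline (BWA-joint) but recovered by the alternate aligner and/or
single-sample genotyping; and the aligner-unique variants are
overwhelmingly very rare (93.7% with BAF ≤ 0.5%, versus 31.5% of shared
variants in the same run) — the signature that makes single-pipeline
calling costly precisely for rare-variant studies. `run_pipeline()` also
writes `summary.json` (all counts/percentages, seed and config hash),
`presence.tsv` (per-variant presence flags and rescue category) and
`variant_metrics.tsv` into the configured output directory.

The packaged curated-table audit:

```r
audit_curated_table(read_curated_table())
# $detected: 9   (APP 1, PSEN1 6, PSEN2 2)
# $undetected: 4
# $undetected_pct: 31
```

A thin command-line front-end over the same functions is installed at
`inst/scripts/rescue_pipeline.R` (`simulate`, `run`, `audit` subcommands).

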