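test_that("histograms conserve their input counts with right-closed bins", {
  h <- make_histogram(c(0, 0.005, 0.01, 0.5, 1), c(0, 0.005, 0.01, 0.5, 1))
  expect_equal(sum(h$counts), 5L)
  # a value exactly at an edge falls in the lower bin (0.005 -> first bin)
  expect_equal(h$counts, c(2L, 1L, 1L, 1L))
  # out-of-range values are clamped into the end bins, NA dropped
  h2 <- make_histogram(c(-1, 2, NA, 0.2), c(0, 0.5, 1))
  expect_equal(sum(h2$counts), 3L)
  expect_equal(h2$counts, c(2L, 1L))
  set.seed(1)
  for (rep in 1:20) {
    x <- runif(100)
    h <- make_histogram(x, seq(0, 1, by = 0.1))
    expect_equal(sum(h$counts), 100L)
  }
})

test_that("bap_values pools carrier allele balance and skips unusable AD", {
  gt <- matrix(c(1L, 2L, 0L, 1L, NA, 1L), 1, 6)
  adr <- matrix(c(5L, 0L, 9L, NA, 3L, 0L), 1, 6)
  ada <- matrix(c(5L, 10L, 1L, 4L, 3L, 0L), 1, 6)
  cs <- make_callset("bap", gt, ad_ref = adr, ad_alt = ada)
  v <- bap_values(cs)
  # carriers: S1 het 5,5 -> 0.5; S2 hom 0,10 -> 1; S4 missing AD skipped;
  # S6 zero-depth skipped; non-carriers and no-calls never contribute
  expect_equal(sort(as.numeric(v)), c(0.5, 1.0))
  expect_equal(attr(v, "n_skipped"), 2L)
  expect_true(all(v >= 0 & v <= 1))

  # enumeration oracle on random call-sets
  set.seed(2)
  for (rep in 1:20) {
    n <- 6
    gt <- matrix(sample(c(0:2, NA), 4 * n, TRUE), 4, n)
    adr <- matrix(sample(c(0:20, NA), 4 * n, TRUE), 4, n)
    ada <- matrix(sample(c(0:20, NA), 4 * n, TRUE), 4, n)
    cs <- make_callset("r", gt, ad_ref = adr, ad_alt = ada)
    manual <- c()
    for (i in 1:4) for (j in 1:n) {
      if (!is.na(gt[i, j]) && gt[i, j] > 0 && !is.na(adr[i, j]) &&
          !is.na(ada[i, j]) && adr[i, j] + ada[i, j] > 0) {
        manual <- c(manual, ada[i, j] / (adr[i, j] + ada[i, j]))
      }
    }
    expect_equal(sort(as.numeric(bap_values(cs))),
                 sort(as.numeric(manual)))
  }
})

test_that("baf counts alt alleles over called genotypes only", {
  # 1 het among 100 called samples -> 0.005
  gt <- matrix(0L, 1, 100); gt[1, 7] <- 1L
  expect_equal(unname(baf(make_callset("b", gt))), 0.005)
  # all hom-alt -> 1
  expect_equal(unname(baf(make_callset("b", matrix(2L, 1, 10)))), 1)
  # 1 het among 50 called of a 100 roster -> 0.01: missing excluded
  gt <- matrix(NA_integer_, 1, 100); gt[1, 1:50] <- 0L; gt[1, 3] <- 1L
  expect_equal(unname(baf(make_callset("b", gt))), 0.01)
  # undefined with zero called genotypes
  expect_error(baf(make_callset("b", matrix(NA_integer_, 1, 5))),
               "zero called")
  # invariant to sample order
  set.seed(4)
  gt <- matrix(sample(c(0:2, NA), 50, TRUE), 5, 10)
  gt[, 1] <- 1L  # ensure every variant has a called genotype
  cs <- make_callset("b", gt)
  perm <- sample(10)
  cs2 <- make_callset("b", gt[, perm], roster = paste0("S", perm))
  expect_equal(unname(baf(cs)), unname(baf(cs2)))
})

test_that("carrier_count counts samples with the alternate allele", {
  gt <- matrix(c(0L, 0L, 0L,
                 1L, 2L, 0L,
                 1L, NA, 2L), 3, 3, byrow = TRUE)
  cs <- make_callset("cc", gt)
  expect_equal(unname(carrier_count(cs)), c(0L, 2L, 2L))
  expect_true(all(carrier_count(cs) <= rowSums(!is.na(gt))))
  # rare-variant binning {1, 2-4, >=5} against hand counts
  gt <- rbind(c(1L, rep(0L, 9)),
              c(1L, 1L, 1L, rep(0L, 7)),
              rep(1L, 10))
  cc <- carrier_count(make_callset("cc", gt))
  expect_equal(unname(cc == 1L), c(TRUE, FALSE, FALSE))
  expect_equal(unname(cc >= 2L & cc <= 4L), c(FALSE, TRUE, FALSE))
  expect_equal(unname(cc >= 5L), c(FALSE, FALSE, TRUE))
})

test_that("gc_flank windows, truncation and N handling match brute force", {
  ref_g <- structure(c("1" = strrep("G", 201)), class = "ReferenceSequence")
  expect_equal(gc_flank(variant_key("1", 101, "G", "A"), ref_g), 1.0)
  ref_at <- structure(c("1" = strrep("AT", 101)), class = "ReferenceSequence")
  expect_equal(gc_flank(variant_key("1", 101, "A", "G"), ref_at), 0.0)

  # brute-force oracle: variant at the center of a 201-base chromosome
  set.seed(6)
  for (rep in 1:50) {
    bases <- sample(c("A", "C", "G", "T", "N"), 201, TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    ref <- structure(c("1" = paste(bases, collapse = "")),
                     class = "ReferenceSequence")
    flank <- bases[c(1:100, 102:201)]
    flank <- flank[flank != "N"]
    expect_equal(gc_flank(variant_key("1", 101, bases[101], "A"), ref),
                 mean(flank %in% c("G", "C")))
    # window truncated at the chromosome start
    flank5 <- bases[c(1:4, 6:105)]
    flank5 <- flank5[flank5 != "N"]
    expect_equal(gc_flank(variant_key("1", 5, bases[5], "A"), ref),
                 mean(flank5 %in% c("G", "C")))
  }
  expect_error(gc_flank("9:5:A:G", ref_g), "not in reference")
})

test_that("region_fraction is exclusive, exhaustive, with BED boundary semantics", {
  lcr0 <- region_set("LCR")
  sdr0 <- region_set("SDR")
  keys <- variant_key("1", 1:10 * 10L, "A", "G")
  rf <- region_fraction(keys, lcr0, sdr0)
  expect_equal(unname(rf$fractions[["other"]]), 1)

  # 10 keys at pos 10,20,...,100: 1 in LCR, 3 in SDR-only
  lcr <- region_set("LCR", "1", 9, 10)            # covers pos 10 only
  sdr <- region_set("SDR", "1", c(9, 19, 29, 39), c(10, 20, 30, 40))
  rf <- region_fraction(keys, lcr, sdr)
  expect_equal(unname(rf$fractions), c(0.1, 0.3, 0.6))
  expect_equal(sum(rf$fractions), 1)
  expect_false(anyNA(rf$category))

  # half-open semantics: interval (P-1, P) contains P; (P, P+1) does not
  p <- 50L
  in_set <- region_set("LCR", "1", p - 1L, p)
  out_set <- region_set("LCR", "1", p, p + 1L)
  key <- variant_key("1", p, "A", "G")
  expect_equal(unname(region_fraction(key, in_set, sdr0)$fractions[["lcr"]]), 1)
  expect_equal(unname(region_fraction(key, out_set, sdr0)$fractions[["lcr"]]), 0)

  expect_error(region_fraction(character(0), lcr0, sdr0), "empty")
})

test_that("titv classifies substitution pairs correctly", {
  expect_error(titv(character(0)), "empty")
  one <- titv(variant_key("1", 1, "A", "G"))
  expect_equal(one$ti, 1L)
  expect_equal(one$tv, 0L)
  expect_true(one$undefined)
  expect_true(is.na(one$ratio))

  # 28 transitions + 10 transversions -> the 2.8 QC threshold value
  keys <- c(variant_key("1", 1:28, "C", "T"),
            variant_key("2", 1:10, "A", "C"))
  expect_equal(titv(keys)$ratio, 2.8)

  # brute-force classification oracle
  set.seed(8)
  for (rep in 1:30) {
    keys <- random_keys(40)
    v <- parse_variant_key(keys)
    is_ti <- (v$ref == "A" & v$alt == "G") | (v$ref == "G" & v$alt == "A") |
      (v$ref == "C" & v$alt == "T") | (v$ref == "T" & v$alt == "C")
    out <- titv(keys)
    expect_equal(out$ti, sum(is_ti))
    expect_equal(out$tv, sum(!is_ti))
  }
})

test_that("build_quality_profile assembles a consistent metric battery", {
  set.seed(10)
  truth <- generate_truth_cohort(small_cohort_model(), seed = 31)
  cs <- emulate_pipeline(truth, noiseless_model(), seed = 5,
                         quality_noise = TRUE)
  cs <- filter_pass_biallelic_snv(cs, 0.9)
  ann <- simulate_annotations(truth$variants, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write.table(ann, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotations(tmp)
  idx <- known_variant_index(list(dbSNP = truth$variants$key[1:100]))
  prof <- build_quality_profile(
    cs, reference = truth$ref_bundle$reference,
    lcr = truth$ref_bundle$lcr, sdr = truth$ref_bundle$sdr,
    annotations = ann, known_index = idx)
  expect_s3_class(prof, "QualityProfile")
  # conservation: every histogram sums to its contributing-value count
  expect_equal(sum(prof$bap_hist$counts), prof$bap_hist$n)
  expect_equal(sum(prof$gq_hist$counts), prof$gq_hist$n)
  expect_equal(sum(prof$baf_hist$counts), n_variants(cs))
  expect_equal(sum(prof$region_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(prof$tier_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(unlist(prof$chrom_counts)), n_variants(cs))
  expect_gte(prof$known_fraction, 0)
  expect_lte(prof$known_fraction, 1)

  # single-sample mode reports carrier counts instead of BAF
  prof_s <- build_quality_profile(cs, mode = "single")
  expect_null(prof_s$baf_hist)
  expect_equal(sum(prof_s$carrier_hist$counts), n_variants(cs))

  # a rare-enriched group has a larger BAF <= 0.5% fraction than a
  # common-enriched group, by construction of the generator
  cc <- carrier_count(cs)
  rare <- cs$variants$key[cc == 1L]
  common <- cs$variants$key[cc >= 5L]
  p_rare <- build_quality_profile(cs, rare)
  p_common <- build_quality_profile(cs, common)
  expect_gt(p_rare$frac_baf_le_005, p_common$frac_baf_le_005)
})

test_that("titv of simulated cohorts recovers the generative odds", {
  model <- cohort_model(n_samples = 20, n_variants = 2000, titv_ratio = 3,
                        chrom_lengths = c("1" = 300000L))
  truth <- generate_truth_cohort(model, seed = 55)
  out <- titv(truth$variants$key)
  p_hat <- out$ti / (out$ti + out$tv)
  se <- sqrt(0.75 * 0.25 / 2000)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})
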