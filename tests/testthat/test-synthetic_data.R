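test_that("truth cohorts have the declared shape and spectrum", {
  model <- small_cohort_model(n_samples = 100L, n_variants = 2000L)
  truth <- generate_truth_cohort(model, seed = 21)
  expect_equal(dim(truth$gt), c(2000L, 100L))
  expect_equal(nrow(truth$variants), 2000L)
  expect_false(anyDuplicated(truth$variants$key) > 0)
  # singleton-class variants sit in exactly one heterozygous carrier
  sing <- truth$variants$singleton
  expect_true(all(rowSums(truth$gt[sing, , drop = FALSE] > 0L) == 1L))
  expect_true(all(truth$gt[sing, , drop = FALSE] <= 1L))
  # realized singleton-class proportion within 3 SE of the model value
  p <- mean(sing)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p - 0.5), 3 * se)
  # empty cohort degenerate case
  empty <- generate_truth_cohort(
    cohort_model(n_samples = 10, n_variants = 0,
                 chrom_lengths = c("1" = 50000L)), seed = 1)
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(dim(empty$gt), c(0L, 10L))
})

test_that("generated references realize the region GC model", {
  all_gc <- cohort_model(n_samples = 10, n_variants = 10,
                         chrom_lengths = c("1" = 20000L),
                         gc_by_region = c(lcr = 1, sdr = 1, other = 1))
  ref <- generate_reference(all_gc, seed = 2)
  expect_true(grepl("^[GC]+$", ref$reference[["1"]]))

  model <- small_cohort_model()
  rb <- generate_reference(model, seed = 3)
  # realized GC in ordinary regions within 3 SE of the model mean
  bases <- strsplit(rb$reference[["1"]], "")[[1]]
  in_special <- rep(FALSE, length(bases))
  for (rs in list(rb$lcr, rb$sdr)) {
    iv <- rs$intervals[rs$intervals$chrom == "1", , drop = FALSE]
    for (j in seq_len(nrow(iv))) {
      in_special[(iv$start[j] + 1):iv$end[j]] <- TRUE
    }
  }
  gc_other <- mean(bases[!in_special] %in% c("G", "C"))
  se <- sqrt(0.45 * 0.55 / sum(!in_special))
  expect_lt(abs(gc_other - 0.45), 3 * se)
  # low-complexity blocks are AT-rich by construction
  if (any(in_special)) {
    gc_lcr_model <- model$gc_by_region[["lcr"]]
    iv <- rb$lcr$intervals[rb$lcr$intervals$chrom == "1", , drop = FALSE]
    if (nrow(iv) > 0) {
      lcr_mask <- rep(FALSE, length(bases))
      for (j in seq_len(nrow(iv))) lcr_mask[(iv$start[j] + 1):iv$end[j]] <- TRUE
      gc_lcr <- mean(bases[lcr_mask] %in% c("G", "C"))
      se <- sqrt(gc_lcr_model * (1 - gc_lcr_model) / sum(lcr_mask))
      expect_lt(abs(gc_lcr - gc_lcr_model), 4 * se)
    }
  }
})

test_that("generators are deterministic under a seed", {
  model <- small_cohort_model(n_samples = 40L, n_variants = 300L)
  t1 <- generate_truth_cohort(model, seed = 9)
  t2 <- generate_truth_cohort(model, seed = 9)
  expect_identical(t1$variants, t2$variants)
  expect_identical(t1$gt, t2$gt)
  expect_identical(t1$ref_bundle$reference, t2$ref_bundle$reference)
  t3 <- generate_truth_cohort(model, seed = 10)
  expect_false(identical(t1$variants, t3$variants))

  pm <- pipeline_model("p", q1 = 0.2)
  c1 <- emulate_pipeline(t1, pm, seed = 4)
  c2 <- emulate_pipeline(t1, pm, seed = 4)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$gq, c2$gq)
  expect_false(identical(c1$variants,
                         emulate_pipeline(t1, pm, seed = 5)$variants))
})

test_that("the noiseless limit recovers exactly the polymorphic truth", {
  truth <- generate_truth_cohort(small_cohort_model(), seed = 17)
  cs <- emulate_pipeline(truth, noiseless_model(), seed = 1)
  poly <- truth$variants$key[rowSums(truth$gt > 0L) > 0L]
  expect_setequal(cs$variants$key, poly)
  expect_true(all(cs$variants$filter == "PASS"))
  # truth carrier counts equal call-set carrier counts in this limit
  expect_equal(unname(carrier_count(cs, poly)),
               unname(rowSums(truth$gt[match(poly, truth$variants$key), ,
                                       drop = FALSE] > 0L)))
  # two identical noiseless pipelines agree completely
  cs2 <- emulate_pipeline(truth, noiseless_model("ideal2"), seed = 99)
  expect_equal(compare_callsets(cs, cs2)$pct_shared, 100)

  expect_error(emulate_pipeline(truth, noiseless_model(), subset = "nope"),
               "outside the cohort")
})

test_that("region-class sensitivity and joint rare dropout are recovered", {
  model <- small_cohort_model(n_samples = 100L, n_variants = 2000L)
  truth <- generate_truth_cohort(model, seed = 41)
  half_sdr <- pipeline_model("half", aligner_sensitivity =
                               c(lcr = 1, sdr = 0.5, other = 1),
                             q1 = 0, pass_mislabel_rate = 0)
  cs <- emulate_pipeline(truth, half_sdr, seed = 6)
  poly <- rowSums(truth$gt > 0L) > 0L
  sdr_keys <- truth$variants$key[poly & truth$variants$region == "sdr"]
  rate <- mean(sdr_keys %in% cs$variants$key)
  se <- sqrt(0.5 * 0.5 / length(sdr_keys))
  expect_lt(abs(rate - 0.5), 4 * se)

  # q_1: fraction of subset singletons missed by joint genotyping
  joint <- pipeline_model("joint", aligner_sensitivity =
                            c(lcr = 1, sdr = 1, other = 1),
                          q1 = 0.3, pass_mislabel_rate = 0)
  cs_j <- emulate_pipeline(truth, joint, seed = 7)
  singles <- truth$variants$key[rowSums(truth$gt > 0L) == 1L]
  miss <- mean(!singles %in% cs_j$variants$key)
  se <- sqrt(0.3 * 0.7 / length(singles))
  expect_lt(abs(miss - 0.3), 4 * se)

  # q_k decays with carrier count and vanishes for common variants
  expect_equal(joint_dropout_prob(joint, 1), 0.3)
  expect_equal(joint_dropout_prob(joint, 2), 0.15)
  expect_lt(joint_dropout_prob(joint, 20), 1e-5)
})

test_that("study bundles are complete, consumable and reproducible", {
  model <- cohort_model(n_samples = 40L, n_variants = 300L,
                        chrom_lengths = c("1" = 100000L, "2" = 100000L))
  pms <- list(pipeline_model("bwa.joint"),
              pipeline_model("novo.joint",
                             aligner_sensitivity = c(lcr = 0.95, sdr = 0.99,
                                                     other = 0.995)),
              pipeline_model("novo.single", genotyping_mode = "single"))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg1 <- generate_study_bundle(model, pms, d1, seed = 33)
  cfg2 <- generate_study_bundle(model, pms, d2, seed = 33)
  files <- c("reference.fa", "lcr.bed", "sdr.bed", "annotations.tsv",
             "sample_metrics.tsv", "truth_variants.tsv",
             "bwa.joint.vcf", "novo.joint.vcf", "novo.single.vcf")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # the bundle feeds the pipeline with zero validation errors
  res <- suppressMessages(run_pipeline(cfg1))
  expect_true(file.exists(res$paths$summary))
  expect_equal(res$comparison$pct_shared + res$comparison$pct_unique_a +
                 res$comparison$pct_unique_b, 100, tolerance = 1e-9)
})
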