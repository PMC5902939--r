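test_that("read_vcf parses records, roster and per-call fields", {
  path <- write_toy_vcf()
  cs <- read_vcf(path, "toy")
  expect_s3_class(cs, "CallSet")
  expect_equal(cs$roster, c("S1", "S2"))
  expect_equal(n_variants(cs), 3L)
  # multi-allelic record retained unmodified
  expect_true("T,G" %in% cs$variants$alt)
  # doses: het, hom-ref; multi-allelic 1/2 counts non-ref alleles; ./. and
  # the half-call ./1 are no-calls
  expect_equal(unname(cs$gt[1, ]), c(1L, 0L))
  expect_equal(unname(cs$gt[2, ]), c(2L, NA_integer_))
  expect_equal(unname(cs$gt[3, ]), c(2L, NA_integer_))
  expect_equal(unname(cs$gq[1, ]), c(50L, 60L))
  expect_true(is.na(cs$gq[3, 2]))    # "." is missing, distinct from zero
  expect_equal(unname(cs$ad_ref[1, ]), c(10L, 25L))
  expect_equal(unname(cs$ad_alt[1, ]), c(10L, 0L))
})

test_that("read_vcf handles GT-only files and rejects malformed input", {
  gt_only <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               paste("1", "5", ".", "A", "T", ".", "PASS", ".", "GT", "0/1",
                     sep = "\t")), gt_only)
  cs <- read_vcf(gt_only, "gtonly")
  expect_true(all(is.na(cs$gq)) && all(is.na(cs$dp)) && all(is.na(cs$ad_ref)))
  expect_equal(unname(cs$gt[1, 1]), 1L)

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tREF"), bad)
  expect_error(read_vcf(bad, "x"), "malformed VCF header")

  dup <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               paste("1", "5", ".", "A", "T", ".", "PASS", ".", "GT", "0/1",
                     sep = "\t"),
               paste("1", "5", ".", "A", "T", ".", "PASS", ".", "GT", "1/1",
                     sep = "\t")), dup)
  expect_error(read_vcf(dup, "x"), "duplicate")
})

test_that("write_vcf then read_vcf is the identity on retained fields", {
  set.seed(7)
  keys <- random_keys(40)
  cs <- random_callset("rt", keys, n_samples = 5L)
  called <- !is.na(cs$gt)
  cs$gq[called] <- sample(0:99, sum(called), replace = TRUE)
  cs$dp[called] <- sample(0:200, sum(called), replace = TRUE)
  cs$ad_ref[called] <- sample(0:50, sum(called), replace = TRUE)
  cs$ad_alt[called] <- sample(0:50, sum(called), replace = TRUE)
  cs$variants$filter[1:5] <- "VQSRTrancheSNP99.90to100.00"
  path <- tempfile(fileext = ".vcf")
  write_vcf(cs, path)
  back <- read_vcf(path, "rt")
  ord <- match(back$variants$key, cs$variants$key)
  expect_setequal(back$variants$key, cs$variants$key)
  expect_equal(back$variants$filter, cs$variants$filter[ord])
  expect_equal(unname(back$gt), unname(cs$gt[ord, ]))
  expect_equal(unname(back$gq), unname(cs$gq[ord, ]))
  expect_equal(unname(back$dp), unname(cs$dp[ord, ]))
  expect_equal(unname(back$ad_ref), unname(cs$ad_ref[ord, ]))
  expect_equal(unname(back$ad_alt), unname(cs$ad_alt[ord, ]))
  # records come back coordinate-sorted
  expect_false(is.unsorted(back$variants$pos[back$variants$chrom == "1"]))
})

test_that("write_vcf emits a header-only file for an empty call-set and dots for missing AD", {
  empty <- make_callset("empty", matrix(integer(0), 0, 2))
  p <- tempfile(fileext = ".vcf")
  write_vcf(empty, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[length(lines)], "^#CHROM")

  one <- make_callset("one", matrix(c(1L, 0L), 1, 2))
  write_vcf(one, p)
  body <- readLines(p)
  body <- body[!startsWith(body, "#")]
  expect_match(body, ":\\.$")  # AD subfield written as "."
})

test_that("read_bed merges overlaps and preserves base-level coverage", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t10", "1\t5\t20"), p)
  rs <- read_bed(p, "LCR")
  expect_equal(rs$intervals,
               data.frame(chrom = "1", start = 0L, end = 20L,
                          stringsAsFactors = FALSE))

  writeLines(character(0), p)
  expect_equal(nrow(read_bed(p, "LCR")$intervals), 0L)

  writeLines("1\t10\t5", p)
  expect_error(read_bed(p, "LCR"), "line 1")

  # base-level oracle: normalized intervals cover exactly the union of
  # input bases, checked by brute force on random intervals
  set.seed(11)
  for (rep in 1:10) {
    start <- sample(0:90, 10, replace = TRUE)
    end <- start + sample(1:10, 10, replace = TRUE)
    writeLines(paste("1", start, end, sep = "\t"), p)
    rs <- read_bed(p, "r")
    covered_oracle <- rep(FALSE, 100)
    for (j in 1:10) covered_oracle[(start[j] + 1):end[j]] <- TRUE
    covered <- rep(FALSE, 100)
    for (j in seq_len(nrow(rs$intervals))) {
      covered[(rs$intervals$start[j] + 1):rs$intervals$end[j]] <- TRUE
    }
    expect_identical(covered, covered_oracle)
    # normalized: sorted, non-overlapping
    expect_true(all(diff(rs$intervals$start) > 0))
    expect_true(all(rs$intervals$start[-1] >
                      rs$intervals$end[-nrow(rs$intervals)] - 1))
  }
})

test_that("read_fasta uppercases, indexes by first header token, validates", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">1 some description", "acgt", ">2", "GGCC"), p)
  ref <- read_fasta(p)
  expect_setequal(names(ref), c("1", "2"))
  expect_equal(ref_base(ref, "1", 1), "A")
  expect_equal(ref_base(ref, "1", 4), "T")
  expect_equal(ref_base(ref, "chr2", 2), "G")  # chr prefix tolerated
  expect_error(ref_base(ref, "9", 1), "not in reference")

  writeLines(c(">1", "ACGT", ">1", "TTTT"), p)
  expect_error(read_fasta(p), "duplicate")
})

test_that("call_rate counts called genotypes over the roster", {
  gt <- matrix(c(1L, 0L, 2L, NA,
                 NA, NA, 0L, 1L), 2, 4, byrow = TRUE)
  cs <- make_callset("cr", gt)
  expect_equal(unname(call_rate(cs)), c(0.75, 0.5))
  # enumeration oracle under random missingness
  set.seed(3)
  for (rep in 1:20) {
    gt <- matrix(sample(c(0L, 1L, 2L, NA), 30, replace = TRUE), 3, 10)
    cs <- make_callset("cr", gt)
    manual <- apply(gt, 1, function(r) sum(!is.na(r)) / 10)
    expect_equal(unname(call_rate(cs)), manual)
  }
})

test_that("filter_pass_biallelic_snv applies the inclusion cascade", {
  # toy set: multi-allelic, indel, non-PASS, low call rate, clean
  v <- data.frame(chrom = "1", pos = 1:5 * 10L,
                  ref = c("A", "AT", "C", "G", "T"),
                  alt = c("G,T", "A", "T", "A", "C"),
                  filter = c("PASS", "PASS", "LowQ", "PASS", "PASS"),
                  stringsAsFactors = FALSE)
  gt <- rbind(rep(1L, 10),
              rep(1L, 10),
              rep(1L, 10),
              c(rep(1L, 8), NA, NA),   # call rate 0.8
              rep(1L, 10))
  cs <- callset("f", paste0("S", 1:10), v, gt)
  out <- filter_pass_biallelic_snv(cs, min_call_rate = 0.9)
  expect_equal(out$variants$key, "1:50:T:C")

  # "at least": call rate exactly at the threshold is retained
  gt_b <- rbind(c(rep(1L, 9), NA))
  cs_b <- make_callset("b", gt_b, roster = paste0("S", 1:10))
  expect_equal(n_variants(filter_pass_biallelic_snv(cs_b, 0.9)), 1L)
  expect_equal(n_variants(filter_pass_biallelic_snv(cs_b, 0.91)), 0L)

  # NULL threshold skips the call-rate criterion entirely
  expect_equal(n_variants(filter_pass_biallelic_snv(cs, NULL)), 2L)
  expect_error(filter_pass_biallelic_snv(cs, 1.5), "min_call_rate")

  # idempotence and subset property
  once <- filter_pass_biallelic_snv(cs, 0.9)
  twice <- filter_pass_biallelic_snv(once, 0.9)
  expect_equal(twice$variants, once$variants)
  expect_true(all(once$variants$key %in% cs$variants$key))
  # input unmodified
  expect_equal(n_variants(cs), 5L)
})
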