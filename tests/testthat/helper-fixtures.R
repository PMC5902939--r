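# Fixtures are built in code at test time; no binary files are shipped.

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", ".", "A", "G", ".", "PASS", ".", "GT:GQ:DP:AD",
          "0/1:50:20:10,10", "0/0:60:25:25,0", sep = "\t"),
    paste("1", "200", ".", "C", "T,G", ".", "PASS", ".", "GT",
          "1/2", "./.", sep = "\t"),
    paste("2", "300", ".", "G", "A", ".", "LowQ", ".", "GT:GQ:DP:AD",
          "1/1:30:10:0,10", "./1:.:.:.", sep = "\t"))
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

# hand-buildable call-set: gt is a variants x samples dose matrix
make_callset <- function(label = "toy", gt,
                         chrom = rep("1", nrow(gt)),
                         pos = seq_len(nrow(gt)) * 100L,
                         ref = rep("A", nrow(gt)),
                         alt = rep("G", nrow(gt)),
                         filter = rep("PASS", nrow(gt)),
                         roster = paste0("S", seq_len(ncol(gt))), ...) {
  callset(label, roster,
          data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     filter = filter, stringsAsFactors = FALSE),
          gt, ...)
}

# a random key universe on one chromosome; alleles vary so ti/tv is mixed
random_keys <- function(n, max_pos = 10 * n) {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1L))
  variant_key("1", pos, ref, alt)
}

random_callset <- function(label, keys, n_samples = 4L, p_missing = 0.1) {
  v <- parse_variant_key(keys)
  gt <- matrix(sample(c(0L, 1L, 2L, NA_integer_), length(keys) * n_samples,
                      replace = TRUE,
                      prob = c((1 - p_missing) * c(0.6, 0.3, 0.1), p_missing)),
               length(keys), n_samples)
  make_callset(label, gt, chrom = v$chrom, pos = v$pos, ref = v$ref,
               alt = v$alt)
}

# small study fixtures shared across tests (built once per test run)
small_cohort_model <- function(n_samples = 120L, n_variants = 800L) {
  cohort_model(n_samples = n_samples, n_variants = n_variants,
               chrom_lengths = c("1" = 200000L, "2" = 200000L))
}

noiseless_model <- function(label = "ideal", mode = "joint") {
  pipeline_model(label,
                 aligner_sensitivity = c(lcr = 1, sdr = 1, other = 1),
                 genotyping_mode = mode, q1 = 0, single_call_dropout = 0,
                 pass_mislabel_rate = 0)
}
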