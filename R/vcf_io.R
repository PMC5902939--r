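#' Read a VCF file into a CallSet
#'
#' Parses a plain-text or gzipped VCF 4.x file (via \pkg{vcfR}) into the
#' matrix-based [callset()] container. The roster is the sample order of the
#' header line. Multi-allelic records are retained unmodified — dropping them
#' is the job of [filter_pass_biallelic_snv()]. FORMAT subfields absent from
#' a record become missing values; a half-called genotype (e.g. \code{"./1"})
#' is a no-call. For multi-allelic genotypes the dose counts non-reference
#' alleles and the AD fields keep the reference and first alternate depths.
#'
#' @param path path to a VCF file with at least one sample column.
#' @param label pipeline configuration tag to attach to the call-set.
#' @return a [callset()].
#' @export
read_vcf <- function(path, label) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  check_vcf_header(path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  roster <- colnames(v@gt)[-1L]
  if (length(roster) == 0L) stop("VCF has no sample columns: ", path)
  nv <- nrow(fix)
  variants <- data.frame(chrom = as.character(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         ref = as.character(fix[, "REF"]),
                         alt = as.character(fix[, "ALT"]),
                         filter = as.character(fix[, "FILTER"]),
                         stringsAsFactors = FALSE)
  variants$filter[is.na(variants$filter)] <- "."
  raw_key <- paste(norm_chrom(variants$chrom), variants$pos,
                   variants$ref, variants$alt, sep = ":")
  if (anyDuplicated(raw_key)) {
    stop("duplicate (chrom,pos,ref,alt) record in ", path, ": ",
         raw_key[duplicated(raw_key)][1L])
  }
  if (nv == 0L) {
    stop("VCF contains no variant records: ", path)
  }
  gt_chr <- extract_fmt(v, "GT")
  gt <- gt_dose_matrix(gt_chr, nv, length(roster))
  num <- function(el) {
    m <- extract_fmt(v, el)
    if (is.null(m)) return(NULL)
    suppressWarnings(matrix(as.integer(m), nv, length(roster)))
  }
  ad <- extract_fmt(v, "AD")
  if (!is.null(ad)) {
    ad[ad == "."] <- NA
    ad_ref <- suppressWarnings(matrix(as.integer(sub(",.*$", "", ad)),
                                      nv, length(roster)))
    ad_alt <- suppressWarnings(matrix(
      as.integer(sub("^[^,]*,([^,]*).*$", "\\1", ad)), nv, length(roster)))
    ad_alt[!grepl(",", ad)] <- NA_integer_
  } else {
    ad_ref <- NULL
    ad_alt <- NULL
  }
  callset(label, roster, variants, gt, gq = num("GQ"), dp = num("DP"),
          ad_ref = ad_ref, ad_alt = ad_alt)
}

# internal: fail early, with the offending line, on a broken VCF header
check_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    n <- n + 1L
    if (length(line) == 0L) stop("malformed VCF header in ", path,
                                 ": no #CHROM line found")
    if (startsWith(line, "#CHROM")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      std <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
      if (length(cols) < 8L || !identical(cols[1:8], std)) {
        stop("malformed VCF header at line ", n, " of ", path, ": ", line)
      }
      return(invisible(TRUE))
    }
    if (!startsWith(line, "##")) {
      stop("malformed VCF header at line ", n, " of ", path, ": ", line)
    }
  }
}

# internal: extract.gt that degrades to NULL when the element is absent
extract_fmt <- function(v, element) {
  out <- tryCatch(vcfR::extract.gt(v, element = element),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  if (all(is.na(out))) return(if (element == "GT") out else NULL)
  out
}

# internal: genotype strings -> alt-allele dose (NA for any half/no-call)
gt_dose_matrix <- function(gt_chr, nv, ns) {
  if (is.null(gt_chr)) return(matrix(NA_integer_, nv, ns))
  u <- unique(as.vector(gt_chr))
  dose_of <- function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  lut <- vapply(u, dose_of, integer(1L))
  matrix(lut[match(as.vector(gt_chr), u)], nv, ns)
}

#' Write a CallSet to a VCF 4.2 file
#'
#' Deterministic writer: records sorted by (chromosome, position), fixed
#' column order, FORMAT always \code{GT:GQ:DP:AD}, missing subfields written
#' as \code{"."}. Round-trips with [read_vcf()] on all retained fields.
#'
#' @param x a [callset()].
#' @param path output path ("-" is not supported); plain text.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "CallSet"))
  ord <- order(chrom_rank(x$variants$chrom), x$variants$pos)
  v <- x$variants[ord, , drop = FALSE]
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt[ord, , drop = FALSE] + 1L],
                   nrow(v), length(x$roster))
  gt_str[is.na(gt_str)] <- "./."
  fmt_na <- function(m) {
    m <- m[ord, , drop = FALSE]
    s <- as.character(m)
    s[is.na(s)] <- "."
    matrix(s, nrow(v), length(x$roster))
  }
  gq <- fmt_na(x$gq)
  dp <- fmt_na(x$dp)
  adr <- x$ad_ref[ord, , drop = FALSE]
  ada <- x$ad_alt[ord, , drop = FALSE]
  ad <- matrix(ifelse(is.na(adr) | is.na(ada), ".",
                      paste(adr, ada, sep = ",")),
               nrow(v), length(x$roster))
  cells <- matrix(paste(gt_str, gq, dp, ad, sep = ":"),
                  nrow(v), length(x$roster))
  body <- if (nrow(v) == 0L) character(0) else
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter, ".",
          "GT:GQ:DP:AD",
          apply(cells, 1L, paste, collapse = "\t"),
          sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$roster), collapse = "\t"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Construct a genomic region set
#'
#' Intervals are BED-convention 0-based half-open. Normalization sorts them
#' and merges overlapping/adjacent intervals per chromosome, which preserves
#' the set of covered bases.
#'
#' @param label region set tag, e.g. "LCR" or "SDR".
#' @param chrom,start,end parallel vectors; start 0-based inclusive, end
#'   exclusive.
#' @return object of class \code{GenomicRegionSet}.
#' @export
region_set <- function(label, chrom = character(0), start = integer(0),
                       end = integer(0)) {
  if (any(start >= end)) stop("region start must be < end")
  if (length(chrom)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      norm_chrom(chrom), IRanges::IRanges(start + 1L, end)))
    intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    ord <- order(chrom_rank(intervals$chrom), intervals$start)
    intervals <- intervals[ord, , drop = FALSE]
    rownames(intervals) <- NULL
  } else {
    intervals <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(label = label, intervals = intervals),
            class = "GenomicRegionSet")
}

#' @method print GenomicRegionSet
#' @export
print.GenomicRegionSet <- function(x, ...) {
  cat(sprintf("GenomicRegionSet '%s': %d intervals, %g bases\n", x$label,
              nrow(x$intervals), sum(x$intervals$end - x$intervals$start)))
  invisible(x)
}

# internal: 1-based GRanges view of a region set
region_granges <- function(rs) {
  GenomicRanges::GRanges(rs$intervals$chrom,
                         IRanges::IRanges(rs$intervals$start + 1L,
                                          rs$intervals$end))
}

#' Read a BED file into a normalized region set
#'
#' @param path BED3+ file, 0-based half-open; empty files give an empty set.
#' @param label region set tag.
#' @return a [region_set()].
#' @export
read_bed <- function(path, label) {
  if (!file.exists(path)) stop("BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(region_set(label))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("BED line with fewer than 3 columns at line ",
         which(lengths(parts) < 3L)[1L], " of ", path)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    stop("invalid BED interval (start >= end or non-numeric) at line ",
         which(bad)[1L], " of ", path)
  }
  region_set(label, chrom, start, end)
}

#' Write a region set as BED3
#' @param rs a [region_set()].
#' @param path output path.
#' @export
write_bed <- function(rs, path) {
  df <- rs$intervals
  writeLines(if (nrow(df)) paste(df$chrom, df$start, df$end, sep = "\t")
             else character(0), path)
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path FASTA file; headers must be unique and sequences non-empty.
#'   The token before the first whitespace is the chromosome label.
#' @return named character vector of uppercased sequences, class
#'   \code{ReferenceSequence}.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  labels <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(labels)) {
    stop("duplicate FASTA header: ", labels[duplicated(labels)][1L])
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence in FASTA: ", labels[Biostrings::width(seqs) == 0L][1L])
  }
  out <- toupper(as.character(seqs))
  names(out) <- norm_chrom(labels)
  structure(out, class = "ReferenceSequence")
}

#' Write a reference to FASTA
#' @param ref a \code{ReferenceSequence} (named character vector).
#' @param path output path.
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Look up one reference base
#' @param ref a \code{ReferenceSequence}.
#' @param chrom chromosome label; \code{pos} 1-based position.
#' @param pos 1-based position.
#' @export
ref_base <- function(ref, chrom, pos) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
  substr(ref[[chrom]], pos, pos)
}

#' Per-variant call rate
#'
#' Fraction of roster samples with a called (both alleles non-missing)
#' genotype.
#'
#' @param x a [callset()].
#' @return named numeric vector in \eqn{[0,1]}, one value per variant.
#' @export
call_rate <- function(x) {
  stopifnot(inherits(x, "CallSet"))
  rowMeans(!is.na(x$gt))
}

#' Apply the variant-level inclusion filter
#'
#' Retains bi-allelic SNVs (single-base REF and ALT, exactly one alternate
#' allele named in the source record) whose FILTER is the literal
#' \code{"PASS"}, and — when \code{min_call_rate} is given — whose call rate
#' is at least that threshold (inclusive boundary). Passing
#' \code{min_call_rate = NULL} skips the call-rate criterion, as appropriate
#' for single-sample genotyping where call rate is not well defined.
#'
#' @param x a [callset()].
#' @param min_call_rate fraction in \eqn{[0,1]} or \code{NULL} (skip).
#' @return a filtered [callset()] (the input is not modified); idempotent.
#' @export
filter_pass_biallelic_snv <- function(x, min_call_rate = NULL) {
  stopifnot(inherits(x, "CallSet"))
  if (!is.null(min_call_rate)) {
    if (!is.numeric(min_call_rate) || length(min_call_rate) != 1L ||
        is.na(min_call_rate) || min_call_rate < 0 || min_call_rate > 1) {
      stop("min_call_rate must be a single number in [0,1] or NULL")
    }
  }
  v <- x$variants
  base <- c("A", "C", "G", "T")
  keep <- v$filter == "PASS" &
    toupper(v$ref) %in% base & toupper(v$alt) %in% base &
    toupper(v$ref) != toupper(v$alt)
  if (!is.null(min_call_rate)) {
    keep <- keep & call_rate(x) >= min_call_rate
  }
  out <- subset_variants(x, which(keep))
  out$variants$ref <- toupper(out$variants$ref)
  out$variants$alt <- toupper(out$variants$alt)
  out
}
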