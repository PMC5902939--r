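#' Build a histogram with fixed bin edges
#'
#' Bins are right-closed (\code{(a,b]}) with the lowest edge included, so a
#' value equal to an edge falls in the lower bin — in particular a B allele
#' frequency of exactly 0.5\% lands in the "<= 0.5\%" first bin. Values
#' outside the edge range are clamped into the end bins so that the bin
#' counts always sum to the number of contributing (non-missing) values.
#'
#' @param values numeric vector; \code{NA}s are dropped.
#' @param edges ascending numeric vector of bin edges (length >= 2).
#' @return list with \code{bin_edges}, \code{counts}, \code{n} (class
#'   \code{Histogram}).
#' @export
make_histogram <- function(values, edges) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  x <- values[!is.na(values)]
  x <- pmin(pmax(x, edges[1L]), edges[length(edges)])
  bin <- as.integer(cut(x, edges, right = TRUE, include.lowest = TRUE))
  structure(list(bin_edges = edges,
                 counts = tabulate(bin, nbins = length(edges) - 1L),
                 n = length(x)),
            class = "Histogram")
}

#' B allele proportions of carrier genotype calls
#'
#' For every (variant, sample) pair in the group where the genotype carries
#' at least one alternate allele and AD is usable (both depths present, sum
#' positive), returns alt_reads / (ref_reads + alt_reads). Values are pooled
#' across the group, not averaged per variant. Carrier calls lacking usable
#' AD are skipped; the skip count is attached as attribute
#' \code{"n_skipped"}.
#'
#' @param x a [callset()].
#' @param keys variant keys to profile (default: all variants in \code{x}).
#' @return numeric vector of proportions in \eqn{[0,1]}.
#' @export
bap_values <- function(x, keys = NULL) {
  stopifnot(inherits(x, "CallSet"))
  i <- if (is.null(keys)) seq_len(nrow(x$variants)) else
    match2(keys, x$variants$key)
  gt <- x$gt[i, , drop = FALSE]
  adr <- x$ad_ref[i, , drop = FALSE]
  ada <- x$ad_alt[i, , drop = FALSE]
  carrier <- !is.na(gt) & gt > 0L
  usable <- carrier & !is.na(adr) & !is.na(ada) & (adr + ada) > 0L
  out <- ada[usable] / (adr[usable] + ada[usable])
  attr(out, "n_skipped") <- sum(carrier & !usable)
  out
}

#' B allele frequency per variant
#'
#' Alternate-allele frequency across called genotypes:
#' (sum of alt-allele doses) / (2 x number of called genotypes). Missing
#' genotypes are excluded from the denominator. Errors if any requested
#' variant has zero called genotypes (the frequency is then undefined).
#'
#' @param x a [callset()].
#' @param keys variant keys (default: all).
#' @return named numeric vector in \eqn{[0,1]}.
#' @export
baf <- function(x, keys = NULL) {
  stopifnot(inherits(x, "CallSet"))
  i <- if (is.null(keys)) seq_len(nrow(x$variants)) else
    match2(keys, x$variants$key)
  gt <- x$gt[i, , drop = FALSE]
  ncalled <- rowSums(!is.na(gt))
  if (any(ncalled == 0L)) {
    stop("BAF undefined: variant with zero called genotypes: ",
         x$variants$key[i][ncalled == 0L][1L])
  }
  rowSums(gt, na.rm = TRUE) / (2 * ncalled)
}

#' Carrier count per variant
#'
#' Number of samples whose called genotype contains at least one alternate
#' allele. A carrier count of 1 defines a singleton.
#'
#' @param x a [callset()].
#' @param keys variant keys (default: all).
#' @return named integer vector.
#' @export
carrier_count <- function(x, keys = NULL) {
  stopifnot(inherits(x, "CallSet"))
  i <- if (is.null(keys)) seq_len(nrow(x$variants)) else
    match2(keys, x$variants$key)
  rowSums(x$gt[i, , drop = FALSE] > 0L, na.rm = TRUE)
}

# internal: match keys, error on unknowns
match2 <- function(keys, universe) {
  i <- match(keys, universe)
  if (anyNA(i)) stop("variant key not in call-set: ", keys[is.na(i)][1L])
  i
}

#' Flanking GC content around variant positions
#'
#' Fraction of G/C bases among up to \code{window} bases on each side of the
#' variant position (the variant base itself is excluded), truncated at
#' chromosome ends. \code{N} bases count in neither numerator nor
#' denominator.
#'
#' @param keys character vector of variant keys.
#' @param reference a \code{ReferenceSequence} from [read_fasta()].
#' @param window flank width per side (default 100 bases each side).
#' @return numeric vector of GC fractions (NA when no usable flank base).
#' @export
gc_flank <- function(keys, reference, window = 100L) {
  stopifnot(window >= 1L)
  v <- parse_variant_key(keys)
  miss <- setdiff(unique(v$chrom), names(reference))
  if (length(miss)) stop("chromosome not in reference: ", miss[1L])
  vapply(seq_len(nrow(v)), function(j) {
    seq <- reference[[v$chrom[j]]]
    len <- nchar(seq)
    pos <- v$pos[j]
    left <- substr(seq, max(1L, pos - window), pos - 1L)
    right <- substr(seq, pos + 1L, min(len, pos + window))
    flank <- strsplit(paste0(left, right), "")[[1L]]
    flank <- flank[flank != "N"]
    if (!length(flank)) return(NA_real_)
    mean(flank %in% c("G", "C"))
  }, numeric(1L))
}

#' Assign variants to LCR / SDR / other region categories
#'
#' Each variant belongs to exactly one category: LCR if its position falls
#' inside any low-complexity interval, else SDR if inside any
#' segmental-duplication interval, else "other" (LCR takes precedence when
#' the two overlap). Membership uses half-open BED semantics: the 1-based
#' position P is inside (start, end] after converting the 0-based interval.
#'
#' @param keys non-empty character vector of variant keys.
#' @param lcr,sdr [region_set()] objects.
#' @return list with \code{fractions} (named: lcr, sdr, other, summing to 1),
#'   \code{category} (per-key factor) and \code{counts}.
#' @export
region_fraction <- function(keys, lcr, sdr) {
  if (length(keys) == 0L) stop("empty variant group")
  v <- parse_variant_key(keys)
  gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- function(rs) {
    if (nrow(rs$intervals) == 0L) return(rep(FALSE, length(keys)))
    GenomicRanges::countOverlaps(gr, region_granges(rs)) > 0L
  }
  in_lcr <- hits(lcr)
  in_sdr <- hits(sdr) & !in_lcr
  category <- factor(ifelse(in_lcr, "lcr", ifelse(in_sdr, "sdr", "other")),
                     levels = c("lcr", "sdr", "other"))
  counts <- table(category)
  list(fractions = stats::setNames(as.numeric(counts) / length(keys),
                                   names(counts)),
       category = category,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Transition/transversion ratio of a variant group
#'
#' Transitions are A<->G and C<->T; every other REF/ALT pair is a
#' transversion. An exome-wide ratio near 2.8–3.0 indicates good call
#' quality; the ratio is undefined (flagged, counts still returned) when
#' there are no transversions.
#'
#' @param keys non-empty character vector of variant keys.
#' @return list with \code{ratio}, \code{ti}, \code{tv}, \code{undefined}.
#' @export
titv <- function(keys) {
  if (length(keys) == 0L) stop("empty variant group")
  v <- parse_variant_key(keys)
  pair <- paste0(v$ref, v$alt)
  ti <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- length(keys) - ti
  list(ratio = if (tv == 0L) NA_real_ else ti / tv,
       ti = ti, tv = tv, undefined = tv == 0L)
}

#' Default histogram bin edges for the quality battery
#'
#' BAP: 20 equal bins on [0,1]; GQ: width-5 bins on [0,100]; DP: log2-spaced;
#' BAF: an explicit "<= 0.5\%" first bin then coarse frequency classes;
#' carrier counts: singleton / 2–4 / >= 5 (the rare-variant classes used when
#' BAF is not computable); GC: 20 equal bins.
#'
#' @return named list of numeric edge vectors.
#' @export
default_quality_bins <- function() {
  list(bap = seq(0, 1, by = 0.05),
       gq = seq(0, 100, by = 5),
       dp = c(0, 2^(0:12)),
       baf = c(0, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5, 1),
       carrier = c(0, 1, 4, 10, 100, 1e9),
       gc = seq(0, 1, by = 0.05))
}

#' Assemble the full quality profile of a variant group
#'
#' Computes the variant quality assessment battery for one group of variants
#' (e.g. the calls unique to one pipeline): pooled carrier allele-balance
#' (BAP), GQ and DP histograms, the B allele frequency spectrum (joint
#' genotyping) or carrier-count spectrum (single-sample genotyping, where
#' no-call and homozygous-reference are indistinguishable so BAF is not
#' computed), chromosome counts, LCR/SDR/other fractions, flanking GC,
#' functional tier composition and the known/novel + high-CADD split.
#' Region, GC, tier and known/novel components are included when the
#' corresponding resource is supplied.
#'
#' @param x the [callset()] containing the group's records.
#' @param keys variant keys of the group (default: all variants of \code{x}).
#' @param group_label label stored in the profile.
#' @param reference optional \code{ReferenceSequence} for flanking GC.
#' @param lcr,sdr optional [region_set()]s.
#' @param annotations optional annotation table from [read_annotations()].
#' @param known_index optional [known_variant_index()].
#' @param mode "joint" (BAF spectrum) or "single" (carrier-count spectrum).
#' @param bins histogram edges, see [default_quality_bins()].
#' @param gc_window flank width per side for GC content.
#' @return a list of class \code{QualityProfile}.
#' @export
build_quality_profile <- function(x, keys = NULL, group_label = x$label,
                                  reference = NULL, lcr = NULL, sdr = NULL,
                                  annotations = NULL, known_index = NULL,
                                  mode = c("joint", "single"),
                                  bins = default_quality_bins(),
                                  gc_window = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "CallSet"))
  if (is.null(keys)) keys <- x$variants$key
  if (length(keys) == 0L) stop("empty variant group")
  prof <- list(group_label = group_label, n_variants = length(keys),
               mode = mode)
  prof$bap_hist <- make_histogram(bap_values(x, keys), bins$bap)
  i <- match2(keys, x$variants$key)
  gt <- x$gt[i, , drop = FALSE]
  called <- !is.na(gt)
  prof$gq_hist <- make_histogram(x$gq[i, , drop = FALSE][called], bins$gq)
  prof$dp_hist <- make_histogram(x$dp[i, , drop = FALSE][called], bins$dp)
  if (mode == "joint") {
    b <- baf(x, keys)
    prof$baf_hist <- make_histogram(b, bins$baf)
    prof$frac_baf_le_005 <- mean(b <= 0.005)
  } else {
    cc <- carrier_count(x, keys)
    prof$carrier_hist <- make_histogram(cc, bins$carrier)
    prof$frac_singleton <- mean(cc == 1L)
    prof$frac_lt5_carriers <- mean(cc < 5L)
  }
  v <- parse_variant_key(keys)
  tab <- table(v$chrom)
  prof$chrom_counts <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(lcr) && !is.null(sdr)) {
    rf <- region_fraction(keys, lcr, sdr)
    prof$region_fractions <- rf$fractions
  }
  if (!is.null(reference)) {
    gc <- gc_flank(keys, reference, gc_window)
    prof$gc_mean <- mean(gc, na.rm = TRUE)
    prof$gc_hist <- make_histogram(gc, bins$gc)
  }
  tt <- titv(keys)
  prof$titv <- tt$ratio
  if (!is.null(annotations)) {
    prof$tier_fractions <- tier_fractions(keys, annotations)
  }
  if (!is.null(known_index)) {
    prof <- c(prof, known_novel_split(keys, known_index, annotations))
  }
  structure(prof, class = "QualityProfile")
}

#' @method print QualityProfile
#' @export
print.QualityProfile <- function(x, ...) {
  cat(sprintf("QualityProfile '%s' (%s mode): %d variants\n",
              x$group_label, x$mode, x$n_variants))
  if (!is.null(x$frac_baf_le_005))
    cat(sprintf("  BAF <= 0.5%%: %.2f%%\n", 100 * x$frac_baf_le_005))
  if (!is.null(x$frac_singleton))
    cat(sprintf("  singletons: %.2f%%  (<5 carriers: %.2f%%)\n",
                100 * x$frac_singleton, 100 * x$frac_lt5_carriers))
  if (!is.null(x$region_fractions))
    cat(sprintf("  LCR %.2f%%  SDR %.2f%%  other %.2f%%\n",
                100 * x$region_fractions[["lcr"]],
                100 * x$region_fractions[["sdr"]],
                100 * x$region_fractions[["other"]]))
  invisible(x)
}
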