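#' Consequence-term vocabulary for functional tiers
#'
#' Tier 1: variants disrupting the start or stop codon or causing splicing
#' events; Tier 2: non-synonymous coding changes; Tier 3: everything else.
#' The mapping uses ANNOVAR-style terms plus common synonyms and is
#' user-extensible — pass a modified copy to [classify_tier()].
#'
#' @return list with character vectors \code{tier1} and \code{tier2}.
#' @export
tier_vocabulary <- function() {
  list(tier1 = c("stopgain", "stoploss", "startloss", "startgain",
                 "start_lost", "stop_gained", "stop_lost", "splicing",
                 "splice_acceptor_variant", "splice_donor_variant"),
       tier2 = c("nonsynonymous SNV", "nonsynonymous_SNV", "nonsynonymous",
                 "missense_variant", "missense"))
}

#' Classify consequence terms into functional tiers
#'
#' The highest tier (1 best) among the supplied terms wins. Unknown terms
#' fall through to Tier 3 with a warning, or raise an error in strict mode.
#'
#' @param consequences character vector of consequence terms for one
#'   variant.
#' @param vocabulary mapping from [tier_vocabulary()].
#' @param strict error on unknown terms instead of warning.
#' @return integer tier in \code{1:3}.
#' @export
classify_tier <- function(consequences, vocabulary = tier_vocabulary(),
                          strict = FALSE) {
  if (length(consequences) == 0L) stop("consequence list must be non-empty")
  known3 <- c("synonymous SNV", "synonymous_SNV", "synonymous", "UTR3",
              "UTR5", "intronic", "intergenic", "ncRNA_exonic",
              "ncRNA_intronic", "upstream", "downstream", "exonic")
  unknown <- setdiff(consequences, c(vocabulary$tier1, vocabulary$tier2,
                                     known3))
  if (length(unknown)) {
    msg <- paste("unknown consequence term(s):",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (any(consequences %in% vocabulary$tier1)) return(1L)
  if (any(consequences %in% vocabulary$tier2)) return(2L)
  3L
}

#' Read a variant annotation table
#'
#' TSV with columns chrom, pos, ref, alt, consequences (";"-separated
#' terms), cadd_phred ("." or NA for missing).
#'
#' @param path TSV path.
#' @return data.frame with a \code{key} column and a \code{consequences}
#'   list-column.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("chrom", "pos", "ref", "alt", "consequences", "cadd_phred")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df$consequences <- strsplit(as.character(df$consequences), ";",
                              fixed = TRUE)
  df$cadd_phred <- as.numeric(df$cadd_phred)
  df
}

#' Tier composition of a variant group
#'
#' @param keys character vector of variant keys.
#' @param annotations table from [read_annotations()].
#' @param ... passed to [classify_tier()].
#' @return named fractions over tier1/tier2/tier3/unannotated, summing to 1.
#' @export
tier_fractions <- function(keys, annotations, ...) {
  if (length(keys) == 0L) stop("empty variant group")
  i <- match(keys, annotations$key)
  tiers <- rep(NA_integer_, length(keys))
  hit <- !is.na(i)
  tiers[hit] <- vapply(annotations$consequences[i[hit]], classify_tier,
                       integer(1L), ...)
  out <- c(tier1 = sum(tiers == 1L, na.rm = TRUE),
           tier2 = sum(tiers == 2L, na.rm = TRUE),
           tier3 = sum(tiers == 3L, na.rm = TRUE),
           unannotated = sum(is.na(tiers)))
  out / length(keys)
}

#' Build a known-variant index
#'
#' Membership is by exact variant key per source (e.g. dbSNP build,
#' ClinVar); a key is "known" when any source contains it.
#'
#' @param sources named list of character key vectors, or (for
#'   [read_known_index()]) named vector of one-key-per-line file paths.
#' @return list of class \code{KnownVariantIndex}.
#' @export
known_variant_index <- function(sources) {
  stopifnot(is.list(sources), !is.null(names(sources)),
            all(nzchar(names(sources))))
  structure(list(sources = lapply(sources, unique)),
            class = "KnownVariantIndex")
}

#' @rdname known_variant_index
#' @export
read_known_index <- function(sources) {
  known_variant_index(lapply(as.list(sources), function(p) {
    keys <- readLines(p)
    keys[nzchar(keys)]
  }))
}

#' Known/novel partition with the high-CADD novel split
#'
#' Splits a variant group into known (present in any index source) and
#' novel, and reports the fraction of the group that is novel with a CADD
#' PHRED score of at least \code{cadd_threshold} (inclusive; CADD >= 20
#' marks the top 1\% most deleterious substitutions). Novel keys without an
#' annotated CADD score cannot enter the high-CADD fraction.
#'
#' @param keys non-empty character vector of variant keys.
#' @param index a [known_variant_index()].
#' @param annotations optional table from [read_annotations()] providing
#'   \code{cadd_phred}.
#' @param cadd_threshold inclusive lower bound (default 20).
#' @return list with \code{known_fraction}, \code{novel_fraction},
#'   \code{novel_high_cadd_fraction}.
#' @export
known_novel_split <- function(keys, index, annotations = NULL,
                              cadd_threshold = 20) {
  if (length(keys) == 0L) stop("empty variant group")
  stopifnot(inherits(index, "KnownVariantIndex"))
  known <- rep(FALSE, length(keys))
  for (src in index$sources) known <- known | keys %in% src
  high_cadd <- rep(FALSE, length(keys))
  if (!is.null(annotations)) {
    cadd <- annotations$cadd_phred[match(keys, annotations$key)]
    high_cadd <- !is.na(cadd) & cadd >= cadd_threshold
  }
  list(known_fraction = mean(known),
       novel_fraction = mean(!known),
       novel_high_cadd_fraction = mean(!known & high_cadd))
}

#' Read the curated pathogenic/protective variant table
#'
#' The packaged default is the transcription of the published table of
#' previously reported pathogenic and protective coding mutations in the
#' three autosomal-dominant early-onset Alzheimer's genes (APP, PSEN1,
#' PSEN2), with each row's external allele frequency and whether the
#' default pipeline (BWA-MEM + multi-sample joint genotyping) called it.
#'
#' @param path TSV with columns gene, protein_change, external_af,
#'   called_by_default; defaults to the packaged table.
#' @return data.frame (class \code{CuratedVariantTable}).
#' @export
read_curated_table <- function(path = system.file("extdata",
                                                  "eoad_table1.tsv",
                                                  package = "rescuevar")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "protein_change", "external_af", "called_by_default")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("curated table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("gene", "protein_change")])) {
    stop("duplicate (gene, protein_change) row in curated table")
  }
  df$called_by_default <- as.logical(df$called_by_default)
  class(df) <- c("CuratedVariantTable", "data.frame")
  df
}

#' Audit the curated variant table against the default pipeline
#'
#' Counts how many of the curated pathogenic/protective variants the
#' default single-pipeline approach detected versus missed, with a per-gene
#' breakdown of the detected rows and the undetected percentage rounded
#' half-up to a whole percent.
#'
#' @param table a [read_curated_table()] data.frame (non-empty).
#' @return list with \code{total}, \code{detected}, \code{undetected},
#'   \code{detected_by_gene}, \code{undetected_by_gene},
#'   \code{undetected_pct}.
#' @export
audit_curated_table <- function(table = read_curated_table()) {
  if (nrow(table) == 0L) stop("curated table is empty")
  det <- table$called_by_default
  genes <- sort(unique(table$gene))
  by_gene <- function(flag) {
    stats::setNames(vapply(genes, function(g) sum(flag & table$gene == g),
                           integer(1L)), genes)
  }
  undetected <- sum(!det)
  list(total = nrow(table),
       detected = sum(det),
       undetected = undetected,
       detected_by_gene = by_gene(det),
       undetected_by_gene = by_gene(!det),
       undetected_pct = floor(100 * undetected / nrow(table) + 0.5))
}
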