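#' Normalize chromosome labels
#'
#' Strips an optional "chr" prefix so GRCh37 resources in either dialect
#' ("chr1" vs "1") can be matched against each other.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without the "chr" prefix.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Build normalized variant keys
#'
#' The identity used for all cross-pipeline matching is the exact tuple
#' (chromosome, 1-based position, reference allele, alternate allele),
#' rendered as \code{"chrom:pos:ref:alt"}. Chromosomes are normalized with
#' [norm_chrom()] and alleles are uppercased; nothing else (rsIDs, windows,
#' genotypes) ever enters the identity.
#'
#' @param chrom,pos,ref,alt vectors of equal length (or length 1, recycled).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

#' Split variant keys back into their fields
#'
#' @param keys character vector of \code{"chrom:pos:ref:alt"} keys.
#' @return data.frame with columns chrom, pos, ref, alt, key.
#' @export
parse_variant_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed variant key(s): ", paste(utils::head(keys[bad], 3), collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
             ref = m[, 3L], alt = m[, 4L], key = keys,
             stringsAsFactors = FALSE)
}

# canonical ordering used by all writers: 1..22, X, Y, MT, then others
chrom_rank <- function(chrom) {
  chrom <- norm_chrom(chrom)
  rank <- suppressWarnings(as.numeric(chrom))
  extra <- c(X = 23, Y = 24, MT = 25, M = 25)
  rank[is.na(rank)] <- extra[chrom[is.na(rank)]]
  rank[is.na(rank)] <- 26 + as.numeric(factor(chrom[is.na(rank)]))
  rank
}

#' Construct a CallSet
#'
#' A CallSet holds one pipeline configuration's variant records over a fixed
#' sample roster: a variant table plus variants-by-samples matrices of
#' genotype dose and the per-call quality fields. The genotype dose is the
#' number of alternate alleles (0, 1, 2) with \code{NA} meaning no-call; a
#' half-call is treated as a no-call. GQ/DP/AD matrices use \code{NA} for
#' missing, which is distinct from zero.
#'
#' @param label pipeline configuration tag (aligner x genotyping mode),
#'   non-empty string.
#' @param roster ordered character vector of sample ids, non-empty.
#' @param variants data.frame with columns chrom, pos, ref, alt, filter.
#' @param gt integer matrix (variants x samples) of alternate-allele doses.
#' @param gq,dp,ad_ref,ad_alt optional matrices of the same shape; missing
#'   matrices are filled with \code{NA}.
#' @return an object of class \code{CallSet}.
#' @export
callset <- function(label, roster, variants, gt,
                    gq = NULL, dp = NULL, ad_ref = NULL, ad_alt = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("callset label must be a non-empty string")
  }
  roster <- as.character(roster)
  if (length(roster) == 0L) stop("callset roster must be non-empty")
  if (anyDuplicated(roster)) stop("duplicate sample ids in roster")
  need <- c("chrom", "pos", "ref", "alt", "filter")
  if (!all(need %in% names(variants))) {
    stop("variants table must have columns: ", paste(need, collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- norm_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys in call-set: ",
         variants$key[duplicated(variants$key)][1L])
  }
  nv <- nrow(variants)
  ns <- length(roster)
  as_mat <- function(m, what) {
    if (is.null(m)) m <- matrix(NA_integer_, nv, ns)
    m <- as.matrix(m)
    if (!all(dim(m) == c(nv, ns))) {
      stop(what, " matrix must be ", nv, " x ", ns)
    }
    dimnames(m) <- list(variants$key, roster)
    m
  }
  obj <- structure(
    list(label = label, roster = roster, variants = variants,
         gt = as_mat(gt, "gt"), gq = as_mat(gq, "gq"), dp = as_mat(dp, "dp"),
         ad_ref = as_mat(ad_ref, "ad_ref"), ad_alt = as_mat(ad_alt, "ad_alt")),
    class = "CallSet")
  obj
}

#' @method print CallSet
#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet '%s': %d variants x %d samples\n",
              x$label, nrow(x$variants), length(x$roster)))
  cat(sprintf("  PASS: %d  non-PASS: %d\n",
              sum(x$variants$filter == "PASS"),
              sum(x$variants$filter != "PASS")))
  invisible(x)
}

#' Variant keys of a call-set or key vector
#'
#' @param x a CallSet or a character vector of keys (returned as-is).
#' @return character vector of variant keys.
#' @export
variant_keys <- function(x) {
  if (inherits(x, "CallSet")) return(x$variants$key)
  if (is.character(x)) return(x)
  stop("cannot extract variant keys from a ", class(x)[1L])
}

#' Number of variants in a call-set
#' @param x a CallSet.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a call-set by variant
#'
#' @param x a CallSet.
#' @param i logical/integer index over variants, or character keys.
#' @return a CallSet with the selected variants, same roster and label.
#' @export
subset_variants <- function(x, i) {
  stopifnot(inherits(x, "CallSet"))
  if (is.character(i)) i <- match(i, x$variants$key)
  if (anyNA(i)) stop("unknown variant key in subset")
  callset(x$label, x$roster,
          x$variants[i, c("chrom", "pos", "ref", "alt", "filter"), drop = FALSE],
          x$gt[i, , drop = FALSE], x$gq[i, , drop = FALSE],
          x$dp[i, , drop = FALSE],
          x$ad_ref[i, , drop = FALSE], x$ad_alt[i, , drop = FALSE])
}

# internal: run expr with a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# internal: fold integers into one reproducible 32-bit seed
mix_seed <- function(...) {
  v <- as.double(unlist(list(...)))
  h <- 17
  for (x in v) h <- (h * 48271 + abs(x) + 11) %% 2147483629
  as.integer(h)
}
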