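#' Compare two call-sets by variant identity
#'
#' Matching is by exact variant key only (genotypes are ignored): counts of
#' keys unique to each side, shared keys, and their percentages of the union.
#'
#' @param a,b [callset()]s or character key vectors.
#' @return list of class \code{ComparisonResult} with fields
#'   \code{label_a/label_b}, counts (\code{unique_a}, \code{unique_b},
#'   \code{shared}, \code{union_size}) and percentages of the union.
#' @export
compare_callsets <- function(a, b) {
  ka <- unique(variant_keys(a))
  kb <- unique(variant_keys(b))
  la <- if (inherits(a, "CallSet")) a$label else "a"
  lb <- if (inherits(b, "CallSet")) b$label else "b"
  shared <- sum(ka %in% kb)
  unique_a <- length(ka) - shared
  unique_b <- length(kb) - shared
  union_size <- unique_a + unique_b + shared
  if (union_size == 0L) stop("empty union: percentages undefined")
  structure(list(label_a = la, label_b = lb,
                 unique_a = unique_a, unique_b = unique_b, shared = shared,
                 union_size = union_size,
                 pct_unique_a = 100 * unique_a / union_size,
                 pct_unique_b = 100 * unique_b / union_size,
                 pct_shared = 100 * shared / union_size),
            class = "ComparisonResult")
}

#' @method print ComparisonResult
#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult %s vs %s (union %d)\n", x$label_a, x$label_b,
              x$union_size))
  cat(sprintf("  unique to %s: %d (%.2f%%)\n", x$label_a, x$unique_a,
              x$pct_unique_a))
  cat(sprintf("  unique to %s: %d (%.2f%%)\n", x$label_b, x$unique_b,
              x$pct_unique_b))
  cat(sprintf("  shared:        %d (%.2f%%)\n", x$shared, x$pct_shared))
  invisible(x)
}

#' Partition the union of two call-sets into unique/shared key groups
#'
#' @param a,b [callset()]s or key vectors.
#' @return list of key vectors \code{unique_a}, \code{unique_b},
#'   \code{shared}.
#' @export
unique_shared_keys <- function(a, b) {
  ka <- unique(variant_keys(a))
  kb <- unique(variant_keys(b))
  list(unique_a = setdiff(ka, kb), unique_b = setdiff(kb, ka),
       shared = intersect(ka, kb))
}

#' Merge call-sets into a union with per-key provenance
#'
#' One entry per key in the union of the inputs; the provenance matrix
#' records which input labels contained each key. Genotypes are carried per
#' source (the source call-sets are kept; no reconciliation into a single
#' genotype is attempted).
#'
#' @param callsets list of [callset()]s with identical rosters (set
#'   \code{reconcile_rosters = TRUE} to allow differing rosters).
#' @param reconcile_rosters allow inputs whose rosters differ.
#' @return list of class \code{MergedCallSet}: union \code{variants} table,
#'   logical \code{presence} matrix (keys x labels), and \code{sources}.
#' @export
union_merge <- function(callsets, reconcile_rosters = FALSE) {
  stopifnot(length(callsets) >= 1L,
            all(vapply(callsets, inherits, TRUE, "CallSet")))
  labels <- vapply(callsets, function(cs) cs$label, "")
  if (anyDuplicated(labels)) stop("duplicate call-set labels in merge")
  if (!reconcile_rosters) {
    r0 <- callsets[[1L]]$roster
    same <- vapply(callsets, function(cs) identical(cs$roster, r0), TRUE)
    if (!all(same)) {
      stop("rosters differ across call-sets; pass reconcile_rosters = TRUE ",
           "to merge anyway")
    }
  }
  all_keys <- unique(unlist(lapply(callsets, variant_keys)))
  presence <- vapply(callsets,
                     function(cs) all_keys %in% cs$variants$key,
                     logical(length(all_keys)))
  presence <- matrix(presence, nrow = length(all_keys),
                     dimnames = list(all_keys, labels))
  # variant fields taken from the first source that contains each key
  first_src <- apply(presence, 1L, function(p) which(p)[1L])
  variants <- do.call(rbind, lapply(seq_along(callsets), function(j) {
    rows <- which(first_src == j)
    cs <- callsets[[j]]
    cs$variants[match(all_keys[rows], cs$variants$key), , drop = FALSE]
  }))
  variants <- variants[match(all_keys, variants$key), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(variants = variants, presence = presence,
                 labels = labels, sources = stats::setNames(callsets, labels)),
            class = "MergedCallSet")
}

#' @method print MergedCallSet
#' @export
print.MergedCallSet <- function(x, ...) {
  cat(sprintf("MergedCallSet: %d keys across %d call-sets (%s)\n",
              nrow(x$variants), length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Describe a repeated-subsampling design
#'
#' Mirrors the study design of drawing each sample size several times and
#' averaging the comparison: default five replicates per size. All
#' randomness flows from the one seed.
#'
#' @param sizes positive integer sample sizes.
#' @param replicates draws per size (default 5).
#' @param seed master seed.
#' @return list of class \code{SubsampleDesign}.
#' @export
subsample_design <- function(sizes, replicates = 5L, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("sizes must be positive")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(sizes = sizes, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "SubsampleDesign")
}

#' Run the repeated-subsampling comparison experiment
#'
#' For each size, draws \code{replicates} subsets of the sample pool
#' uniformly without replacement, invokes both pipeline providers on each
#' subset, compares the resulting call-sets, and summarizes the percentage
#' of shared/unique variants per size (mean and SD over replicates).
#'
#' Seeding: the subset for (size, replicate) derives deterministically from
#' the design seed, size and replicate index, so any cell can be re-run in
#' isolation; the provider seed derives from the subset content, so
#' identical subsets (e.g. every replicate at the full pool size) yield
#' identical call-sets and zero SD.
#'
#' @param pool character vector of available sample ids.
#' @param pipelines named list of exactly two provider functions
#'   \code{function(subset, seed)} returning a [callset()] (see
#'   [pipeline_provider()]).
#' @param design a [subsample_design()]; all sizes must be <= the pool size.
#' @return list of class \code{SubsampleSummary} with \code{replicates}
#'   (per-draw rows) and \code{summary} (per-size mean/SD) data frames.
#' @export
subsample_experiment <- function(pool, pipelines, design) {
  stopifnot(inherits(design, "SubsampleDesign"))
  if (length(pipelines) != 2L) {
    stop("subsample_experiment compares exactly two pipelines")
  }
  if (is.null(names(pipelines)) || any(!nzchar(names(pipelines)))) {
    names(pipelines) <- c("a", "b")
  }
  if (any(design$sizes > length(pool))) {
    stop("subsample size exceeds pool size (", length(pool), ")")
  }
  rows <- list()
  for (size in design$sizes) {
    for (rep in seq_len(design$replicates)) {
      subset_seed <- mix_seed(design$seed, size, rep)
      subset <- with_seed(subset_seed, sample(pool, size))
      # canonicalize to pool order: the draw is a set, and providers must
      # see identical input for identical subsets
      idx <- sort(match(subset, pool))
      subset <- pool[idx]
      css <- lapply(seq_along(pipelines), function(j) {
        pseed <- mix_seed(design$seed, j, sum(idx * seq_along(idx)),
                          length(idx))
        tryCatch(pipelines[[j]](subset, pseed), error = function(e) {
          stop(sprintf("pipeline '%s' failed at size %d replicate %d: %s",
                       names(pipelines)[j], size, rep, conditionMessage(e)),
               call. = FALSE)
        })
      })
      cmp <- compare_callsets(css[[1L]], css[[2L]])
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, replicate = rep,
        unique_a = cmp$unique_a, unique_b = cmp$unique_b,
        shared = cmp$shared, union_size = cmp$union_size,
        pct_unique_a = cmp$pct_unique_a, pct_unique_b = cmp$pct_unique_b,
        pct_shared = cmp$pct_shared)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- function(col, f) {
    as.numeric(tapply(reps[[col]], reps$size, f))
  }
  sizes <- sort(unique(reps$size))
  summary <- data.frame(
    size = sizes,
    mean_pct_shared = agg("pct_shared", mean),
    sd_pct_shared = agg("pct_shared", stats::sd),
    mean_pct_unique_a = agg("pct_unique_a", mean),
    sd_pct_unique_a = agg("pct_unique_a", stats::sd),
    mean_pct_unique_b = agg("pct_unique_b", mean),
    sd_pct_unique_b = agg("pct_unique_b", stats::sd))
  structure(list(replicates = reps, summary = summary, design = design,
                 labels = names(pipelines)),
            class = "SubsampleSummary")
}

#' @method print SubsampleSummary
#' @export
print.SubsampleSummary <- function(x, ...) {
  cat(sprintf("SubsampleSummary: %s vs %s, %d replicates/size\n",
              x$labels[1L], x$labels[2L], x$design$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Categorize the 2x2 rescue of variants missed by the default pipeline
#'
#' Takes the default pipeline's call-set plus up to three alternative
#' call-sets (alternate aligner with joint genotyping; single-sample
#' genotyping; alternate aligner with single-sample genotyping) and labels
#' every key of the union: \code{shared_all} (in every provided set),
#' \code{default_only}, \code{other} (in default plus a proper subset of the
#' alternatives), \code{rescued_by_aligner} (absent from default, present in
#' the alternate aligner's joint set but no single-sample set),
#' \code{rescued_by_genotyping} (absent from the joint sets, present in a
#' single-sample set), and \code{rescued_by_both} (absent from default,
#' present in both the alternate aligner's set and a single-sample set).
#' Categories partition the union; full presence flags are reported so the
#' categories can be re-cut.
#'
#' @param default the default pipeline's [callset()] or key vector.
#' @param alt_aligner,single_gt,alt_single_gt alternative call-sets or key
#'   vectors; at least one must be provided.
#' @return list of class \code{RescueResult} with a per-key \code{table}
#'   (presence flags + category) and \code{counts}.
#' @export
rescue_sets <- function(default, alt_aligner = NULL, single_gt = NULL,
                        alt_single_gt = NULL) {
  sets <- list(default = default, alt_aligner = alt_aligner,
               single_gt = single_gt, alt_single_gt = alt_single_gt)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  if (length(sets) < 2L) stop("rescue_sets needs at least two call-sets")
  keysets <- lapply(sets, function(s) unique(variant_keys(s)))
  all_keys <- unique(unlist(keysets))
  flags <- vapply(keysets, function(k) all_keys %in% k,
                  logical(length(all_keys)))
  flags <- matrix(flags, nrow = length(all_keys),
                  dimnames = list(all_keys, names(keysets)))
  in_def <- flags[, "default"]
  in_alt <- if ("alt_aligner" %in% colnames(flags)) flags[, "alt_aligner"]
            else rep(FALSE, length(all_keys))
  single_cols <- intersect(c("single_gt", "alt_single_gt"), colnames(flags))
  in_single <- if (length(single_cols))
    rowSums(flags[, single_cols, drop = FALSE]) > 0L
  else rep(FALSE, length(all_keys))
  in_all <- rowSums(flags) == ncol(flags)
  category <- character(length(all_keys))
  category[in_def & in_all] <- "shared_all"
  category[in_def & !in_all & rowSums(flags) == 1L] <- "default_only"
  category[in_def & !in_all & rowSums(flags) > 1L] <- "other"
  category[!in_def & in_alt & in_single] <- "rescued_by_both"
  category[!in_def & in_alt & !in_single] <- "rescued_by_aligner"
  category[!in_def & !in_alt & in_single] <- "rescued_by_genotyping"
  levels <- c("shared_all", "default_only", "other", "rescued_by_aligner",
              "rescued_by_genotyping", "rescued_by_both")
  category <- factor(category, levels = levels)
  tab <- data.frame(key = all_keys, as.data.frame(flags),
                    category = category, stringsAsFactors = FALSE,
                    row.names = NULL)
  counts <- stats::setNames(as.integer(table(category)), levels)
  structure(list(table = tab, counts = counts,
                 n_union = length(all_keys),
                 n_rescued = sum(!in_def)),
            class = "RescueResult")
}

#' @method print RescueResult
#' @export
print.RescueResult <- function(x, ...) {
  cat(sprintf("RescueResult: union %d keys, %d (%.2f%%) absent from default\n",
              x$n_union, x$n_rescued, 100 * x$n_rescued / x$n_union))
  print(x$counts)
  invisible(x)
}

#' Write a comparison / rescue report as TSV
#'
#' One row per key with presence flags (and category for rescue results).
#'
#' @param x a \code{RescueResult} or \code{MergedCallSet}.
#' @param path output TSV path.
#' @export
write_report_tsv <- function(x, path) {
  df <- if (inherits(x, "RescueResult")) x$table
        else if (inherits(x, "MergedCallSet"))
          data.frame(key = rownames(x$presence), as.data.frame(x$presence),
                     row.names = NULL)
        else stop("unsupported report object: ", class(x)[1L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
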