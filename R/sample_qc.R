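#' Method-of-moments inbreeding coefficient (PLINK-style F)
#'
#' Computes \eqn{F = (O_{hom} - E_{hom}) / (m - E_{hom})} where
#' \eqn{O_{hom}} is the observed number of homozygous sites for the sample
#' and \eqn{E_{hom} = \sum_i (1 - 2 p_i (1 - p_i))} is its Hardy–Weinberg
#' expectation given the per-site alternate allele frequencies. Applied to
#' X-chromosome genotypes this is the sex-check statistic: genetic males
#' (hemizygous X) appear fully "inbred" (F near 1), females near 0.
#'
#' @param genotypes integer vector of alt-allele doses (0/1/2; \code{NA}
#'   sites are dropped together with their frequencies).
#' @param allele_freqs per-site alternate allele frequencies in (0,1).
#' @return a single numeric F estimate.
#' @export
inbreeding_f <- function(genotypes, allele_freqs) {
  if (length(genotypes) != length(allele_freqs)) {
    stop("genotypes and allele_freqs must have equal length")
  }
  keep <- !is.na(genotypes)
  g <- genotypes[keep]
  p <- allele_freqs[keep]
  if (length(g) < 1L) stop("need at least one called site")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must lie in (0,1)")
  if (!all(g %in% 0:2)) stop("genotype doses must be 0, 1 or 2")
  m <- length(g)
  o_hom <- sum(g != 1L)
  e_hom <- sum(1 - 2 * p * (1 - p))
  denom <- m - e_hom
  if (denom == 0) stop("F undefined: m equals expected homozygous count")
  (o_hom - e_hom) / denom
}

#' Default sample-QC thresholds
#'
#' The cascade's defaults: coverage (>= 10x over at least 90\% of target and
#' >= 40x over at least 30\%), per-sample call rate >= 95\%, per-sample Ti/Tv
#' >= 2.8, contamination fail iff FREEMIX strictly exceeds 0.02, and the sex
#' check (reported males fail when F < 0.7, reported females when F > 0.3).
#' "At least" criteria are inclusive; the contamination and sex inequalities
#' are strict, as worded.
#'
#' @return named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(min_frac_10x = 0.90, min_frac_40x = 0.30,
       min_call_rate = 0.95, min_titv = 2.8, max_freemix = 0.02,
       male_min_f = 0.7, female_max_f = 0.3)
}

qc_criteria <- c("coverage", "call_rate", "titv", "contamination",
                 "sex_check", "apoe", "relatedness", "ancestry", "batch")

#' Apply the sample-level and population-level QC cascade
#'
#' Evaluates every criterion for every sample of a metrics table (columns:
#' \code{sample_id}, \code{frac_target_ge_10x}, \code{frac_target_ge_40x},
#' \code{call_rate}, \code{titv}, \code{freemix}, \code{sex_f},
#' \code{reported_sex}, \code{apoe_match}, \code{relatedness_flag},
#' \code{ancestry_flag}, \code{batch_flag}). A sample may fail several
#' criteria and is counted once per criterion it fails; the retained set is
#' the samples failing none. A missing required metric makes that criterion
#' indeterminate: with \code{strict_missing = TRUE} (default) the sample is
#' excluded with reason "missing_metric", otherwise the criterion passes.
#' Samples with reported sex "unknown" are retained on the sex criterion
#' (indeterminate, counted separately).
#'
#' @param metrics data.frame of per-sample metrics, unique sample_id.
#' @param thresholds list from [qc_thresholds()].
#' @param strict_missing how to treat missing metrics (see above).
#' @return list of class \code{QCReport}: per-sample logical failure table,
#'   per-criterion removal counts, retained and removed id vectors.
#' @export
apply_sample_qc <- function(metrics, thresholds = qc_thresholds(),
                            strict_missing = TRUE) {
  stopifnot(is.data.frame(metrics), "sample_id" %in% names(metrics))
  if (anyDuplicated(metrics$sample_id)) stop("duplicate sample_id in metrics")
  n <- nrow(metrics)
  th <- utils::modifyList(qc_thresholds(), thresholds)
  fail <- matrix(FALSE, n, length(qc_criteria),
                 dimnames = list(metrics$sample_id, qc_criteria))
  indeterminate <- matrix(FALSE, n, length(qc_criteria),
                          dimnames = dimnames(fail))
  crit <- function(name, value) {
    indeterminate[, name] <<- is.na(value)
    fail[, name] <<- !is.na(value) & value
  }
  crit("coverage", !(metrics$frac_target_ge_10x >= th$min_frac_10x &
                       metrics$frac_target_ge_40x >= th$min_frac_40x))
  crit("call_rate", metrics$call_rate < th$min_call_rate)
  crit("titv", metrics$titv < th$min_titv)
  crit("contamination", metrics$freemix > th$max_freemix)
  sex <- as.character(metrics$reported_sex)
  sex_fail <- ifelse(sex == "male", metrics$sex_f < th$male_min_f,
                     ifelse(sex == "female", metrics$sex_f > th$female_max_f,
                            NA))
  # unknown reported sex: indeterminate but retained on this criterion
  sex_unknown <- !sex %in% c("male", "female")
  crit("sex_check", sex_fail)
  indeterminate[sex_unknown, "sex_check"] <- FALSE
  crit("apoe", !metrics$apoe_match)
  crit("relatedness", as.logical(metrics$relatedness_flag))
  crit("ancestry", as.logical(metrics$ancestry_flag))
  crit("batch", as.logical(metrics$batch_flag))
  missing_metric <- rowSums(indeterminate) > 0L
  removed <- rowSums(fail) > 0L
  if (strict_missing) removed <- removed | missing_metric
  report <- data.frame(sample_id = metrics$sample_id, as.data.frame(fail),
                       missing_metric = missing_metric,
                       sex_indeterminate = sex_unknown,
                       retained = !removed, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(
    per_sample = report,
    criterion_counts = colSums(fail),
    n_missing_metric = sum(missing_metric),
    n_sex_indeterminate = sum(sex_unknown),
    retained = metrics$sample_id[!removed],
    removed = metrics$sample_id[removed],
    thresholds = th, strict_missing = strict_missing),
    class = "QCReport")
}

#' @method print QCReport
#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d retained, %d removed\n",
              length(x$retained), length(x$removed)))
  cc <- x$criterion_counts[x$criterion_counts > 0L]
  for (nm in names(cc)) cat(sprintf("  %-14s %d\n", nm, cc[[nm]]))
  if (x$n_missing_metric)
    cat(sprintf("  %-14s %d\n", "missing_metric", x$n_missing_metric))
  invisible(x)
}

#' Read / write a sample metrics table
#'
#' Tab-separated with the documented header (see [apply_sample_qc()]).
#'
#' @param path TSV path.
#' @return data.frame of per-sample metrics.
#' @export
read_sample_metrics <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("sample_id", "frac_target_ge_10x", "frac_target_ge_40x",
            "call_rate", "titv", "freemix", "sex_f", "reported_sex",
            "apoe_match", "relatedness_flag", "ancestry_flag", "batch_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metrics table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_sample_metrics
#' @param metrics data.frame to write.
#' @export
write_sample_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a QC report
#' @param report a \code{QCReport}.
#' @param tsv_path,json_path output paths (either may be \code{NULL}).
#' @export
write_qc_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_sample, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      criterion_counts = as.list(report$criterion_counts),
      n_missing_metric = report$n_missing_metric,
      n_retained = length(report$retained),
      n_removed = length(report$removed)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
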