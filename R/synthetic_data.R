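#' Specify the generative model for a synthetic cohort
#'
#' The model describes the statistical structure the simulator must
#' reproduce: an exome-like, heavily rare-skewed allele frequency spectrum
#' (a point mass of singleton-class variants plus a Beta-distributed MAF
#' tail), variant placement across low-complexity (LCR),
#' segmental-duplication (SDR) and ordinary regions, and region-dependent
#' flanking GC composition.
#'
#' @param n_samples,n_variants cohort dimensions.
#' @param prop_singleton proportion of variants in the singleton class
#'   (exactly one heterozygous carrier in the full cohort).
#' @param maf_beta shape parameters of the Beta MAF distribution for the
#'   non-singleton mass (truncated to \eqn{[1/(2n), 0.5]}).
#' @param titv_ratio target transition/transversion ratio of simulated
#'   alleles (P(transition) = ratio / (ratio + 1)).
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param region_var_fracs target fractions of variant positions in
#'   lcr/sdr/other (sums to 1).
#' @param region_base_fracs fractions of genome bases assigned to LCR and
#'   SDR blocks.
#' @param gc_by_region mean flanking GC per region class.
#' @param seed default seed for generators that are not given one.
#' @return list of class \code{CohortModel}.
#' @export
cohort_model <- function(n_samples = 500L, n_variants = 5000L,
                         prop_singleton = 0.5, maf_beta = c(1.5, 8),
                         titv_ratio = 3,
                         chrom_lengths = c("1" = 600000L, "2" = 600000L,
                                           "3" = 600000L, "4" = 600000L),
                         region_var_fracs = c(lcr = 0.005, sdr = 0.04,
                                              other = 0.955),
                         region_base_fracs = c(lcr = 0.01, sdr = 0.05),
                         gc_by_region = c(lcr = 0.30, sdr = 0.45,
                                          other = 0.45),
                         seed = 1L) {
  stopifnot(n_samples >= 1L, n_variants >= 0L,
            prop_singleton >= 0, prop_singleton <= 1,
            length(maf_beta) == 2L, all(maf_beta > 0),
            all(chrom_lengths > 0),
            all(c("lcr", "sdr", "other") %in% names(region_var_fracs)),
            abs(sum(region_var_fracs) - 1) < 1e-9,
            all(region_base_fracs >= 0), sum(region_base_fracs) < 1,
            all(gc_by_region >= 0 & gc_by_region <= 1))
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 prop_singleton = prop_singleton, maf_beta = maf_beta,
                 titv_ratio = titv_ratio,
                 chrom_lengths = chrom_lengths,
                 region_var_fracs = region_var_fracs[c("lcr", "sdr", "other")],
                 region_base_fracs = region_base_fracs,
                 gc_by_region = gc_by_region, seed = as.integer(seed)),
            class = "CohortModel")
}

#' Specify a per-pipeline detection model
#'
#' Emulates one aligner x genotyping-strategy configuration without
#' touching reads. Aligners differ through region-class detection
#' sensitivities (mainly inside segmental duplications). Joint genotyping
#' additionally drops a variant with a carrier-count-indexed probability
#' \eqn{q_k = q_1 d^{k-1}} — the minimal model of cross-sample evidence
#' deeming the few supporting reads of a very rare allele insignificant, so
#' \eqn{q_k \to 0} for common variants. Single-sample genotyping instead
#' retains each carrier's site-call independently and emits the variant if
#' at least one carrier call survives. Surviving calls get DP from a
#' negative binomial, AD binomial given DP and true genotype, GQ a capped
#' function of DP, and FILTER is PASS except for a small mislabel rate.
#'
#' @param label pipeline configuration tag.
#' @param aligner_sensitivity named detection probabilities per region
#'   class (lcr, sdr, other).
#' @param genotyping_mode "joint" or "single".
#' @param q1 joint-genotyping miss probability for singletons (carrier
#'   count 1); \code{q_decay} the geometric decay per extra carrier.
#' @param single_call_dropout per-carrier-call miss probability in
#'   single-sample mode.
#' @param dp_mu,dp_size negative-binomial depth parameters.
#' @param gq_cap GQ ceiling (GQ = min(cap, 3 DP)).
#' @param pass_mislabel_rate probability a true call is labeled non-PASS.
#' @return list of class \code{PipelineModel}.
#' @export
pipeline_model <- function(label,
                           aligner_sensitivity = c(lcr = 0.95, sdr = 0.97,
                                                   other = 0.998),
                           genotyping_mode = c("joint", "single"),
                           q1 = 0.3, q_decay = 0.5,
                           single_call_dropout = 0.02,
                           dp_mu = 60, dp_size = 8, gq_cap = 99L,
                           pass_mislabel_rate = 0.01) {
  genotyping_mode <- match.arg(genotyping_mode)
  stopifnot(is.character(label), nzchar(label),
            all(c("lcr", "sdr", "other") %in% names(aligner_sensitivity)),
            all(aligner_sensitivity >= 0 & aligner_sensitivity <= 1),
            q1 >= 0, q1 <= 1, q_decay >= 0, q_decay <= 1,
            single_call_dropout >= 0, single_call_dropout <= 1,
            pass_mislabel_rate >= 0, pass_mislabel_rate <= 1)
  structure(list(label = label,
                 aligner_sensitivity =
                   aligner_sensitivity[c("lcr", "sdr", "other")],
                 genotyping_mode = genotyping_mode,
                 q1 = q1, q_decay = q_decay,
                 single_call_dropout = single_call_dropout,
                 dp_mu = dp_mu, dp_size = dp_size, gq_cap = gq_cap,
                 pass_mislabel_rate = pass_mislabel_rate),
            class = "PipelineModel")
}

#' Joint-genotyping dropout probability for a carrier count
#' @param model a [pipeline_model()].
#' @param k integer carrier count(s).
#' @return miss probabilities \eqn{q_k} (0 for k < 1).
#' @export
joint_dropout_prob <- function(model, k) {
  ifelse(k >= 1L, model$q1 * model$q_decay^(pmax(k, 1L) - 1L), 0)
}

#' Generate a synthetic reference with LCR/SDR annotation
#'
#' Tiles each chromosome into 2 kb blocks, assigns blocks to region classes
#' at the model's base fractions, draws bases with the per-class GC
#' composition, and returns the sequence together with the realized LCR and
#' SDR interval sets (merged, BED semantics). Deterministic under the seed.
#'
#' @param model a [cohort_model()].
#' @param seed integer seed (default: the model's).
#' @return list with \code{reference} (a \code{ReferenceSequence}),
#'   \code{lcr} and \code{sdr} ([region_set()]s).
#' @export
generate_reference <- function(model, seed = model$seed) {
  stopifnot(inherits(model, "CohortModel"))
  with_seed(mix_seed(seed, 101), {
    block <- 2000L
    probs <- c(model$region_base_fracs[["lcr"]],
               model$region_base_fracs[["sdr"]],
               1 - sum(model$region_base_fracs))
    seqs <- character(0)
    bed <- list(lcr = list(), sdr = list())
    for (chrom in names(model$chrom_lengths)) {
      len <- as.integer(model$chrom_lengths[[chrom]])
      starts <- seq.int(0L, len - 1L, by = block)
      ends <- pmin(starts + block, len)
      cls <- sample(c("lcr", "sdr", "other"), length(starts),
                    replace = TRUE, prob = probs)
      parts <- vapply(seq_along(starts), function(b) {
        gc <- model$gc_by_region[[cls[b]]]
        n <- ends[b] - starts[b]
        paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                     prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
              collapse = "")
      }, character(1L))
      seqs[[chrom]] <- paste(parts, collapse = "")
      for (rc in c("lcr", "sdr")) {
        hit <- cls == rc
        if (any(hit)) {
          bed[[rc]][[chrom]] <- data.frame(chrom = chrom,
                                           start = starts[hit],
                                           end = ends[hit])
        }
      }
    }
    as_set <- function(rc) {
      df <- do.call(rbind, bed[[rc]])
      if (is.null(df)) region_set(toupper(rc))
      else region_set(toupper(rc), df$chrom, df$start, df$end)
    }
    list(reference = structure(seqs, class = "ReferenceSequence"),
         lcr = as_set("lcr"), sdr = as_set("sdr"))
  })
}

# internal: sample n distinct 1-based positions from a region set's bases
sample_positions <- function(intervals, n) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  widths <- intervals$end - intervals$start
  total <- sum(widths)
  if (total < n) stop("not enough positions in region class: need ", n,
                      ", have ", total)
  offs <- sample.int(total, n)
  cum <- cumsum(widths)
  iv <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
  data.frame(chrom = intervals$chrom[iv],
             pos = as.integer(intervals$start[iv] +
                                (offs - c(0L, cum)[iv])))
}

#' Generate the simulation ground truth: variants and genotypes
#'
#' Draws variant positions per region class at the model's target
#' fractions, assigns each variant a true MAF from the mixture spectrum
#' (singleton-class variants are placed in exactly one heterozygous
#' carrier), and samples genotypes independently per sample under
#' Hardy–Weinberg at the realized MAF. Reference alleles come from the
#' generated reference sequence; alternate alleles follow the model's
#' transition/transversion odds.
#'
#' @param model a [cohort_model()].
#' @param ref_bundle output of [generate_reference()]; generated from the
#'   model when \code{NULL}.
#' @param seed integer seed (default: the model's).
#' @return list of class \code{TruthCohort}: \code{variants} table (key,
#'   region class, true MAF, singleton flag), genotype-dose matrix
#'   \code{gt} (variants x samples), \code{samples}, and the reference
#'   bundle.
#' @export
generate_truth_cohort <- function(model, ref_bundle = NULL,
                                  seed = model$seed) {
  stopifnot(inherits(model, "CohortModel"))
  if (is.null(ref_bundle)) ref_bundle <- generate_reference(model, seed)
  with_seed(mix_seed(seed, 202), {
    ns <- model$n_samples
    nv <- model$n_variants
    samples <- sprintf("S%05d", seq_len(ns))
    if (nv == 0L) {
      return(structure(list(
        variants = data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              key = character(0), region = character(0),
                              true_maf = numeric(0), singleton = logical(0)),
        gt = matrix(0L, 0L, ns, dimnames = list(NULL, samples)),
        samples = samples, model = model, ref_bundle = ref_bundle),
        class = "TruthCohort"))
    }
    # per-class variant counts (largest class absorbs rounding remainder
    # and any shortfall when a class realized too few bases)
    counts <- round(nv * model$region_var_fracs)
    avail <- c(lcr = sum(ref_bundle$lcr$intervals$end -
                           ref_bundle$lcr$intervals$start),
               sdr = sum(ref_bundle$sdr$intervals$end -
                           ref_bundle$sdr$intervals$start))
    counts[["lcr"]] <- min(counts[["lcr"]], avail[["lcr"]])
    counts[["sdr"]] <- min(counts[["sdr"]], avail[["sdr"]])
    counts[["other"]] <- nv - counts[["lcr"]] - counts[["sdr"]]
    whole <- GenomicRanges::GRanges(
      names(model$chrom_lengths),
      IRanges::IRanges(1L, as.integer(model$chrom_lengths)))
    special <- rbind(ref_bundle$lcr$intervals, ref_bundle$sdr$intervals)
    covered <- if (nrow(special)) {
      region_granges(region_set("covered", special$chrom, special$start,
                                special$end))
    } else GenomicRanges::GRanges()
    other_gr <- GenomicRanges::setdiff(whole, covered)
    other_iv <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(other_gr)),
      start = GenomicRanges::start(other_gr) - 1L,
      end = GenomicRanges::end(other_gr))
    class_block <- function(intervals, n, region) {
      df <- sample_positions(intervals, n)
      df$region <- rep(region, nrow(df))
      df
    }
    pos_tab <- rbind(
      class_block(ref_bundle$lcr$intervals, counts[["lcr"]], "lcr"),
      class_block(ref_bundle$sdr$intervals, counts[["sdr"]], "sdr"),
      class_block(other_iv, counts[["other"]], "other"))
    # duplicate positions are possible across draws only within a class
    # (sample.int is without replacement), so keys are unique by design
    ref <- vapply(seq_len(nrow(pos_tab)), function(j) {
      ref_base(ref_bundle$reference, pos_tab$chrom[j], pos_tab$pos[j])
    }, character(1L))
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    p_ti <- model$titv_ratio / (model$titv_ratio + 1)
    is_ti <- stats::runif(nrow(pos_tab)) < p_ti
    alt <- ifelse(is_ti, transition[ref],
                  vapply(ref, function(b) sample(transversions[[b]], 1L),
                         character(1L)))
    singleton <- stats::runif(nrow(pos_tab)) < model$prop_singleton
    maf <- numeric(nrow(pos_tab))
    maf[singleton] <- 1 / (2 * ns)
    n_poly <- sum(!singleton)
    maf[!singleton] <- pmin(0.5, pmax(1 / (2 * ns),
                                      stats::rbeta(n_poly, model$maf_beta[1L],
                                                   model$maf_beta[2L])))
    gt <- matrix(0L, nrow(pos_tab), ns, dimnames = list(NULL, samples))
    if (n_poly > 0L) {
      gt[!singleton, ] <- matrix(
        stats::rbinom(n_poly * ns, 2L, maf[!singleton]), n_poly, ns)
    }
    if (any(singleton)) {
      gt[cbind(which(singleton),
               sample.int(ns, sum(singleton), replace = TRUE))] <- 1L
    }
    variants <- data.frame(chrom = pos_tab$chrom, pos = pos_tab$pos,
                           ref = unname(ref), alt = unname(alt),
                           region = pos_tab$region, true_maf = maf,
                           singleton = singleton, stringsAsFactors = FALSE)
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
    ord <- order(chrom_rank(variants$chrom), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    gt <- gt[ord, , drop = FALSE]
    rownames(gt) <- variants$key
    structure(list(variants = variants, gt = gt, samples = samples,
                   model = model, ref_bundle = ref_bundle),
              class = "TruthCohort")
  })
}

#' @method print TruthCohort
#' @export
print.TruthCohort <- function(x, ...) {
  cat(sprintf("TruthCohort: %d variants x %d samples (%.1f%% singleton-class)\n",
              nrow(x$variants), length(x$samples),
              100 * mean(x$variants$singleton)))
  invisible(x)
}

#' Emulate one pipeline configuration on a sample subset
#'
#' Applies the pipeline's detection model to every truth variant that is
#' polymorphic within the subset: region-class aligner sensitivity first,
#' then either the joint-genotyping carrier-count dropout \eqn{q_k} or
#' independent per-carrier-call retention for single-sample genotyping.
#' Surviving records receive simulated GQ/DP/AD (unless
#' \code{quality_noise = FALSE}, which leaves them missing) and a FILTER
#' label (PASS except at the mislabel rate). In single-sample mode
#' non-carrier genotypes are emitted as no-calls, since a same-as-reference
#' call cannot be distinguished from no call there. Deterministic under the
#' seed.
#'
#' @param truth a [generate_truth_cohort()] cohort.
#' @param pipeline a [pipeline_model()].
#' @param subset sample ids to genotype (default: the full cohort).
#' @param seed integer seed.
#' @param quality_noise draw GQ/DP/AD for emitted calls.
#' @return a [callset()] labeled with the pipeline tag.
#' @export
emulate_pipeline <- function(truth, pipeline, subset = NULL, seed = 1L,
                             quality_noise = TRUE) {
  stopifnot(inherits(truth, "TruthCohort"), inherits(pipeline, "PipelineModel"))
  if (is.null(subset)) subset <- truth$samples
  if (!all(subset %in% truth$samples)) {
    stop("subset contains samples outside the cohort: ",
         subset[!subset %in% truth$samples][1L])
  }
  with_seed(mix_seed(seed, 303), {
    sub_gt <- truth$gt[, subset, drop = FALSE]
    k <- rowSums(sub_gt > 0L)
    nv <- nrow(sub_gt)
    sens <- pipeline$aligner_sensitivity[truth$variants$region]
    detected <- (k > 0L) & (stats::runif(nv) < sens)
    if (pipeline$genotyping_mode == "joint") {
      qk <- joint_dropout_prob(pipeline, k)
      keep <- detected & (stats::runif(nv) >= qk)
      gt_out <- sub_gt[keep, , drop = FALSE]
    } else {
      carrier <- sub_gt > 0L
      surv <- carrier &
        matrix(stats::runif(length(sub_gt)) >= pipeline$single_call_dropout,
               nv, ncol(sub_gt))
      keep <- detected & (rowSums(surv) > 0L)
      gt_out <- sub_gt[keep, , drop = FALSE]
      gt_out[!surv[keep, , drop = FALSE]] <- NA_integer_
    }
    v <- truth$variants[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    nkeep <- nrow(v)
    v$filter <- ifelse(stats::runif(nkeep) < pipeline$pass_mislabel_rate,
                       "VQSRTrancheSNP99.90to100.00", "PASS")
    ns <- length(subset)
    if (quality_noise && nkeep > 0L) {
      dp <- matrix(stats::rnbinom(nkeep * ns, mu = pipeline$dp_mu,
                                  size = pipeline$dp_size), nkeep, ns)
      err <- c(0.005, 0.5, 0.99)
      dose <- gt_out
      dose[is.na(dose)] <- 0L
      ad_alt <- matrix(stats::rbinom(nkeep * ns, as.vector(dp),
                                     err[as.vector(dose) + 1L]), nkeep, ns)
      ad_ref <- dp - ad_alt
      gq <- pmin(3L * dp, pipeline$gq_cap)  # pmin keeps dims of 1st arg
      nocall <- is.na(gt_out)
      dp[nocall] <- NA_integer_
      gq[nocall] <- NA_integer_
      ad_ref[nocall] <- NA_integer_
      ad_alt[nocall] <- NA_integer_
    } else {
      dp <- gq <- ad_ref <- ad_alt <- NULL
    }
    callset(pipeline$label, subset, v, gt_out, gq = gq, dp = dp,
            ad_ref = ad_ref, ad_alt = ad_alt)
  })
}

#' Wrap a truth cohort + pipeline model as a subsampling provider
#'
#' Returns the \code{function(subset, seed)} interface that
#' [subsample_experiment()] invokes: emulate the pipeline on the subset,
#' then apply the variant inclusion filter (PASS bi-allelic SNVs, with the
#' call-rate criterion only when \code{min_call_rate} is given).
#'
#' @param truth a [generate_truth_cohort()] cohort.
#' @param model a [pipeline_model()].
#' @param min_call_rate passed to [filter_pass_biallelic_snv()].
#' @param quality_noise draw per-call GQ/DP/AD (not needed for key-level
#'   comparisons; defaults off for speed).
#' @return a provider function.
#' @export
pipeline_provider <- function(truth, model, min_call_rate = NULL,
                              quality_noise = FALSE) {
  force(truth); force(model); force(min_call_rate); force(quality_noise)
  function(subset, seed) {
    cs <- emulate_pipeline(truth, model, subset, seed,
                           quality_noise = quality_noise)
    filter_pass_biallelic_snv(cs, min_call_rate)
  }
}

#' Simulate a per-sample QC metrics table
#'
#' Produces mostly-passing metrics with a configurable number of planted
#' failures per criterion (coverage, call rate, contamination, sex check),
#' for exercising [apply_sample_qc()].
#'
#' @param sample_ids character vector of sample ids.
#' @param seed integer seed.
#' @param n_fail named integer vector of planted failure counts.
#' @return data.frame in the [read_sample_metrics()] schema.
#' @export
simulate_sample_metrics <- function(sample_ids, seed = 1L,
                                    n_fail = c(coverage = 2L, call_rate = 1L,
                                               contamination = 1L,
                                               sex_check = 1L)) {
  n <- length(sample_ids)
  with_seed(mix_seed(seed, 404), {
    df <- data.frame(
      sample_id = sample_ids,
      frac_target_ge_10x = round(stats::runif(n, 0.92, 0.99), 4),
      frac_target_ge_40x = round(stats::runif(n, 0.35, 0.80), 4),
      call_rate = round(stats::runif(n, 0.96, 0.999), 4),
      titv = round(stats::runif(n, 2.85, 3.1), 3),
      freemix = round(stats::runif(n, 0, 0.015), 4),
      sex_f = NA_real_,
      reported_sex = sample(c("male", "female"), n, replace = TRUE),
      apoe_match = TRUE,
      relatedness_flag = FALSE, ancestry_flag = FALSE, batch_flag = FALSE,
      stringsAsFactors = FALSE)
    df$sex_f[df$reported_sex == "male"] <-
      round(stats::runif(sum(df$reported_sex == "male"), 0.9, 1), 3)
    df$sex_f[df$reported_sex == "female"] <-
      round(stats::runif(sum(df$reported_sex == "female"), -0.1, 0.1), 3)
    pool <- sample(seq_len(n))
    take <- function(k) {
      k <- min(k, length(pool))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    df$frac_target_ge_10x[take(n_fail[["coverage"]])] <- 0.80
    df$call_rate[take(n_fail[["call_rate"]])] <- 0.90
    df$freemix[take(n_fail[["contamination"]])] <- 0.05
    i <- take(n_fail[["sex_check"]])
    df$sex_f[i] <- ifelse(df$reported_sex[i] == "male", 0.5, 0.6)
    df
  })
}

#' Simulate an annotation table for a set of truth variants
#'
#' Assigns one ANNOVAR-style consequence term per variant at exome-like
#' proportions and a CADD PHRED score whose distribution depends on the
#' functional tier.
#'
#' @param variants truth variant table (chrom, pos, ref, alt).
#' @param seed integer seed.
#' @return data.frame with columns chrom, pos, ref, alt, consequences,
#'   cadd_phred.
#' @export
simulate_annotations <- function(variants, seed = 1L) {
  n <- nrow(variants)
  with_seed(mix_seed(seed, 505), {
    terms <- c("stopgain", "splicing", "stoploss", "nonsynonymous SNV",
               "synonymous SNV", "UTR3", "UTR5", "intronic")
    probs <- c(0.010, 0.010, 0.005, 0.400, 0.350, 0.100, 0.050, 0.075)
    cons <- sample(terms, n, replace = TRUE, prob = probs)
    tier <- ifelse(cons %in% c("stopgain", "splicing", "stoploss"), 1L,
                   ifelse(cons == "nonsynonymous SNV", 2L, 3L))
    mu <- c(33, 20, 8)[tier]
    sd <- c(6, 7, 6)[tier]
    cadd <- round(pmax(0, stats::rnorm(n, mu, sd)), 2)
    data.frame(chrom = variants$chrom, pos = variants$pos,
               ref = variants$ref, alt = variants$alt,
               consequences = cons, cadd_phred = cadd,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete on-disk synthetic study bundle
#'
#' Writes everything [run_pipeline()] consumes: the reference FASTA, LCR
#' and SDR BEDs, one VCF per pipeline model (emulated on the full cohort),
#' the annotation TSV, known-variant key lists, a sample-metrics TSV, and
#' the retained truth tables for oracle checks, plus a JSON run
#' configuration. Regenerating with the same seed reproduces identical
#' files.
#'
#' @param model a [cohort_model()].
#' @param pipeline_models list of at least two [pipeline_model()]s with
#'   unique labels.
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @return the [run_config()] for the bundle, invisibly.
#' @export
generate_study_bundle <- function(model, pipeline_models, out_dir,
                                  seed = model$seed) {
  stopifnot(inherits(model, "CohortModel"), length(pipeline_models) >= 2L)
  labels <- vapply(pipeline_models, function(p) p$label, "")
  if (anyDuplicated(labels)) stop("pipeline model labels must be unique")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth_cohort(model, seed = seed)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    lcr = file.path(out_dir, "lcr.bed"),
    sdr = file.path(out_dir, "sdr.bed"),
    annotations = file.path(out_dir, "annotations.tsv"),
    metrics = file.path(out_dir, "sample_metrics.tsv"),
    truth = file.path(out_dir, "truth_variants.tsv"))
  write_fasta(truth$ref_bundle$reference, paths$reference)
  write_bed(truth$ref_bundle$lcr, paths$lcr)
  write_bed(truth$ref_bundle$sdr, paths$sdr)
  vcfs <- character(0)
  modes <- character(0)
  for (j in seq_along(pipeline_models)) {
    pm <- pipeline_models[[j]]
    cs <- emulate_pipeline(truth, pm, seed = mix_seed(seed, 600 + j))
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", pm$label),
                                   ".vcf"))
    write_vcf(cs, p)
    vcfs[pm$label] <- p
    modes[pm$label] <- pm$genotyping_mode
  }
  ann <- simulate_annotations(truth$variants, seed = mix_seed(seed, 700))
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  known <- with_seed(mix_seed(seed, 800), {
    is_known <- stats::runif(nrow(truth$variants)) < 0.75
    list(dbSNP147 = truth$variants$key[is_known],
         ExAC = truth$variants$key[is_known & stats::runif(nrow(truth$variants)) < 0.5],
         ClinVar = truth$variants$key[is_known & stats::runif(nrow(truth$variants)) < 0.05])
  })
  known_paths <- character(0)
  for (src in names(known)) {
    p <- file.path(out_dir, paste0("known_", src, ".txt"))
    writeLines(known[[src]], p)
    known_paths[src] <- p
  }
  write_sample_metrics(
    simulate_sample_metrics(truth$samples, seed = mix_seed(seed, 900)),
    paths$metrics)
  tv <- truth$variants
  tv$carrier_count <- rowSums(truth$gt > 0L)
  utils::write.table(tv, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- run_config(vcfs = vcfs, modes = modes,
                    reference = paths$reference,
                    lcr_bed = paths$lcr, sdr_bed = paths$sdr,
                    annotations = paths$annotations,
                    known_index = known_paths,
                    sample_metrics = paths$metrics,
                    min_call_rate = 0.9,
                    out_dir = file.path(out_dir, "results"),
                    seed = seed)
  write_run_config(cfg, file.path(out_dir, "bundle_config.json"))
  invisible(cfg)
}
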