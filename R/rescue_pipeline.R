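#' Build a pipeline run configuration
#'
#' Collects the inputs of one end-to-end analysis: the per-pipeline VCFs
#' (named by configuration label; the first label is the default pipeline,
#' the second the alternate aligner, any further ones the single-sample
#' genotyping sets for the 2x2 rescue), per-label genotyping modes, the
#' resources for variant profiling, the variant inclusion threshold, the
#' output directory and the seed recorded in every output.
#'
#' @param vcfs named character vector label -> VCF path (>= 2 entries).
#' @param modes named character vector label -> "joint" or "single";
#'   missing labels default to "joint". The call-rate criterion is applied
#'   to joint call-sets only.
#' @param reference,lcr_bed,sdr_bed,annotations optional resource paths.
#' @param known_index named character vector source -> key-list path.
#' @param sample_metrics optional per-sample metrics TSV.
#' @param curated_table optional curated variant TSV for the audit.
#' @param min_call_rate call-rate threshold for joint call-sets, or
#'   \code{NULL} to skip.
#' @param out_dir output directory.
#' @param seed integer seed recorded in outputs.
#' @return list of class \code{RunConfig}.
#' @export
run_config <- function(vcfs, modes = NULL, reference = NULL, lcr_bed = NULL,
                       sdr_bed = NULL, annotations = NULL,
                       known_index = NULL, sample_metrics = NULL,
                       curated_table = NULL, min_call_rate = 0.9,
                       out_dir = "rescuevar_out", seed = 1L) {
  vcfs <- unlist(vcfs)
  if (length(vcfs) < 2L) stop("need at least two labeled VCFs")
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs)))) {
    stop("vcfs must be named by pipeline label")
  }
  if (anyDuplicated(names(vcfs))) stop("duplicate pipeline labels")
  all_modes <- stats::setNames(rep("joint", length(vcfs)), names(vcfs))
  if (!is.null(modes)) {
    bad <- setdiff(names(modes), names(vcfs))
    if (length(bad)) stop("mode given for unknown label: ", bad[1L])
    if (!all(modes %in% c("joint", "single"))) {
      stop("modes must be 'joint' or 'single'")
    }
    all_modes[names(modes)] <- modes
  }
  structure(list(vcfs = vcfs, modes = all_modes, reference = reference,
                 lcr_bed = lcr_bed, sdr_bed = sdr_bed,
                 annotations = annotations,
                 known_index = unlist(known_index),
                 sample_metrics = sample_metrics,
                 curated_table = curated_table,
                 min_call_rate = min_call_rate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Serialize / load a run configuration as JSON
#' @param config a [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must become objects, not arrays, to keep their labels
  for (nm in c("vcfs", "modes", "known_index")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(vcfs = raw$vcfs, modes = raw$modes, reference = raw$reference,
             lcr_bed = raw$lcr_bed, sdr_bed = raw$sdr_bed,
             annotations = raw$annotations, known_index = raw$known_index,
             sample_metrics = raw$sample_metrics,
             curated_table = raw$curated_table,
             min_call_rate = raw$min_call_rate,
             out_dir = raw$out_dir, seed = raw$seed)
}

# internal: provenance hash of a config, independent of the output dir
config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# internal: condense a Histogram for the JSON summary
hist_json <- function(h) {
  if (is.null(h)) return(NULL)
  list(bin_edges = h$bin_edges, counts = h$counts, n = h$n)
}

profile_json <- function(p) {
  if (is.null(p)) return(NULL)
  out <- list(group_label = p$group_label, n_variants = p$n_variants,
              mode = p$mode,
              bap_hist = hist_json(p$bap_hist), gq_hist = hist_json(p$gq_hist),
              dp_hist = hist_json(p$dp_hist), baf_hist = hist_json(p$baf_hist),
              carrier_hist = hist_json(p$carrier_hist),
              frac_baf_le_005 = p$frac_baf_le_005,
              frac_singleton = p$frac_singleton,
              frac_lt5_carriers = p$frac_lt5_carriers,
              chrom_counts = as.list(p$chrom_counts),
              region_fractions = as.list(p$region_fractions),
              gc_mean = p$gc_mean, titv = p$titv,
              tier_fractions = as.list(p$tier_fractions),
              known_fraction = p$known_fraction,
              novel_fraction = p$novel_fraction,
              novel_high_cadd_fraction = p$novel_high_cadd_fraction)
  out[!vapply(out, is.null, TRUE)]
}

#' Run the full comparison / rescue / profiling pipeline
#'
#' Executes the analysis end to end on a [run_config()]: read and filter
#' each call-set (PASS bi-allelic SNVs; call-rate threshold for joint sets),
#' compare the first two call-sets, categorize the 2x2 rescue when more
#' sets are provided, profile the unique and shared variant groups with
#' every available resource, run the sample QC cascade and the curated
#' table audit when their inputs are configured, and write deterministic
#' outputs (a JSON summary embedding the seed and a config hash, plus
#' per-key TSV reports) into the output directory. Identical configuration
#' and seed reproduce byte-identical summaries.
#'
#' @param config a [run_config()] (or path to one serialized as JSON).
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  missing_vcf <- !file.exists(config$vcfs)
  if (any(missing_vcf)) {
    stop("VCF for pipeline '", names(config$vcfs)[missing_vcf][1L],
         "' not found: ", config$vcfs[missing_vcf][1L])
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  labels <- names(config$vcfs)
  filter_counts <- list()
  callsets <- stage("read_filter", {
    out <- list()
    for (lab in labels) {
      raw <- read_vcf(config$vcfs[[lab]], lab)
      mcr <- if (config$modes[[lab]] == "joint") config$min_call_rate
             else NULL
      flt <- filter_pass_biallelic_snv(raw, mcr)
      message(sprintf("[%s] %d records read, %d retained after filtering",
                      lab, n_variants(raw), n_variants(flt)))
      filter_counts[[lab]] <- list(read = n_variants(raw),
                                   retained = n_variants(flt))
      out[[lab]] <- flt
    }
    out
  })
  reference <- if (!is.null(config$reference))
    stage("resources", read_fasta(config$reference)) else NULL
  lcr <- if (!is.null(config$lcr_bed))
    stage("resources", read_bed(config$lcr_bed, "LCR")) else NULL
  sdr <- if (!is.null(config$sdr_bed))
    stage("resources", read_bed(config$sdr_bed, "SDR")) else NULL
  annotations <- if (!is.null(config$annotations))
    stage("resources", read_annotations(config$annotations)) else NULL
  known <- if (length(config$known_index))
    stage("resources", read_known_index(config$known_index)) else NULL

  cmp <- stage("compare",
               compare_callsets(callsets[[1L]], callsets[[2L]]))
  rescue <- if (length(callsets) >= 3L) {
    stage("rescue", rescue_sets(
      default = callsets[[1L]], alt_aligner = callsets[[2L]],
      single_gt = callsets[[3L]],
      alt_single_gt = if (length(callsets) >= 4L) callsets[[4L]] else NULL))
  } else NULL

  groups <- unique_shared_keys(callsets[[1L]], callsets[[2L]])
  prof_for <- function(keys, cs, lab) {
    if (length(keys) == 0L) return(NULL)
    mode <- if (config$modes[[cs$label]] == "single") "single" else "joint"
    build_quality_profile(cs, keys, group_label = lab,
                          reference = reference, lcr = lcr, sdr = sdr,
                          annotations = annotations, known_index = known,
                          mode = mode)
  }
  profiles <- stage("profile", list(
    unique_a = prof_for(groups$unique_a, callsets[[1L]],
                        paste0(labels[1L], "-unique")),
    unique_b = prof_for(groups$unique_b, callsets[[2L]],
                        paste0(labels[2L], "-unique")),
    shared = prof_for(groups$shared, callsets[[1L]], "shared")))

  qc <- if (!is.null(config$sample_metrics)) {
    stage("sample_qc",
          apply_sample_qc(read_sample_metrics(config$sample_metrics)))
  } else NULL
  audit <- if (!is.null(config$curated_table)) {
    stage("audit", audit_curated_table(read_curated_table(config$curated_table)))
  } else NULL

  merged <- stage("merge", union_merge(unname(callsets),
                                       reconcile_rosters = TRUE))
  paths <- list(summary = file.path(config$out_dir, "summary.json"),
                presence = file.path(config$out_dir, "presence.tsv"),
                metrics = file.path(config$out_dir, "variant_metrics.tsv"))
  stage("write", {
    if (!is.null(rescue)) {
      write_report_tsv(rescue, paths$presence)
    } else {
      write_report_tsv(merged, paths$presence)
    }
    write_variant_metrics(merged, paths$metrics, lcr = lcr, sdr = sdr,
                          reference = reference, annotations = annotations,
                          known = known)
    summary <- list(
      seed = config$seed,
      config_hash = config_hash(config),
      labels = labels,
      filter_counts = filter_counts,
      comparison = unclass(cmp),
      rescue_counts = if (!is.null(rescue)) as.list(rescue$counts) else NULL,
      profiles = lapply(profiles, profile_json),
      sample_qc = if (!is.null(qc)) list(
        criterion_counts = as.list(qc$criterion_counts),
        n_retained = length(qc$retained),
        n_removed = length(qc$removed)) else NULL,
      curated_audit = if (!is.null(audit)) list(
        total = audit$total, detected = audit$detected,
        undetected = audit$undetected,
        detected_by_gene = as.list(audit$detected_by_gene),
        undetected_pct = audit$undetected_pct) else NULL)
    summary <- summary[!vapply(summary, is.null, TRUE)]
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  })
  invisible(list(callsets = callsets, comparison = cmp, rescue = rescue,
                 profiles = profiles, sample_qc = qc, curated_audit = audit,
                 merged = merged, paths = paths))
}

# internal: per-variant metric table over the union of call-sets
write_variant_metrics <- function(merged, path, lcr = NULL, sdr = NULL,
                                  reference = NULL, annotations = NULL,
                                  known = NULL) {
  keys <- merged$variants$key
  df <- data.frame(key = keys, stringsAsFactors = FALSE)
  first_src <- apply(merged$presence, 1L, function(p) which(p)[1L])
  cc <- rep(NA_integer_, length(keys))
  bafv <- rep(NA_real_, length(keys))
  for (j in seq_along(merged$sources)) {
    rows <- which(first_src == j)
    if (!length(rows)) next
    cs <- merged$sources[[j]]
    cc[rows] <- carrier_count(cs, keys[rows])
    called <- rowSums(!is.na(cs$gt[match2(keys[rows], cs$variants$key), ,
                                   drop = FALSE]))
    ok <- called > 0L
    if (any(ok)) bafv[rows[ok]] <- baf(cs, keys[rows][ok])
  }
  df$carrier_count <- cc
  df$baf <- bafv
  if (!is.null(lcr) && !is.null(sdr)) {
    df$region <- as.character(region_fraction(keys, lcr, sdr)$category)
  }
  if (!is.null(reference)) df$gc_flank <- gc_flank(keys, reference)
  if (!is.null(annotations)) {
    i <- match(keys, annotations$key)
    df$tier <- NA_integer_
    hit <- !is.na(i)
    df$tier[hit] <- vapply(annotations$consequences[i[hit]],
                           classify_tier, integer(1L))
    df$cadd_phred <- annotations$cadd_phred[i]
  }
  if (!is.null(known)) {
    kn <- rep(FALSE, length(keys))
    for (src in known$sources) kn <- kn | keys %in% src
    df$known <- kn
  }
  for (lab in colnames(merged$presence)) {
    df[[paste0("in_", gsub("[^A-Za-z0-9._]", "_", lab))]] <-
      merged$presence[, lab]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
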