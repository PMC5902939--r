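Package: rescuevar
Title: Multi-Pipeline Variant Call-Set Comparison and Rescue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares VCF call-sets produced by different aligner and
    genotyping-strategy combinations, quantifies and characterizes the
    variants each single pipeline misses ("rescued" variants), and profiles
    variant groups with a battery of quality metrics (allele balance, B
    allele frequency, carrier counts, genotype quality, depth, flanking GC
    content, low-complexity and segmental-duplication region overlap,
    transition/transversion ratio, functional tiers, known/novel status).
    Includes the exome sample-level QC cascade (coverage, call rate, Ti/Tv,
    contamination, sex check), a repeated-subsampling experiment over sample
    sizes, and a generative simulator of cohort genotype matrices and
    per-pipeline detection so the whole analysis is reproducible on
    synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
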