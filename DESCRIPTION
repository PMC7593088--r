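Package: pioneerscan
Title: Pioneer-Factor Analysis of Transcription-Factor Binding in Open and
    Closed Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor ChIP-seq and
    ATAC-seq peak sets to characterize pioneer-factor behaviour:
    classification of binding sites as open or closed chromatin by
    accessibility overlap, genomic-feature distributions, position
    weight matrix motif enrichment by chromatin class, differential peak
    occupancy between genotypes with false discovery rate control,
    integration of closed-chromatin binding with temporal differential
    expression, and exact cohort statistics for variant positional
    clustering and genotype-phenotype association. Includes seeded
    synthetic-data generators with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
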