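Package: haplofoot
Title: Overlap of eQTL and GWAS Haplotypes with DNase-seq Transcription
    Factor Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies what fraction of eQTL- and GWAS-associated
    haplotypes can be explained by variants inside DNase-seq transcription
    factor footprints. Provides linkage-disequilibrium haplotype expansion
    from a phased panel, footprint quality control including a DNase
    cut-profile artefact filter, conservation-based footprint score
    calibration, workspace-constrained permutation enrichment with
    empirical p-values, the haplotype overlap proportion statistic across
    r-squared thresholds and nested annotation layers, exact-p-value
    position weight matrix scanning with a motif-disruption test, and a
    seedable synthetic-data generator with planted effect sizes so the
    whole pipeline is testable without external genomic downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
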