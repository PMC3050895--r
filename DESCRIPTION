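Package: activeflora
Title: Metatranscriptomic Triage and Profiling of the Active Gut Microbiota
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing community cDNA (metatranscriptome) reads
    from the human gut: step-wise sorting of reads into small-subunit rRNA,
    large-subunit rRNA and non-ribosomal fractions with calibrated
    Karlin-Altschul E-value thresholds; naive-Bayes taxonomic classification
    of 16S transcripts with bootstrap confidence and lowest-common-ancestor
    binning of protein hits; family-level richness and diversity estimation
    (rarefaction, Chao1, ACE, Shannon, correspondence analysis); COG
    functional profiling with rate-ratio enrichment; position-weight-matrix
    small-RNA detection; and accounting of the uncharacterized fraction.
    Includes a self-contained ungapped seed-and-extend homology search with
    exact gapless Karlin-Altschul statistics and a synthetic-community read
    simulator with truth labels, so the whole pipeline is testable end to
    end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
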