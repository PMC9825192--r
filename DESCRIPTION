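Package: chromsplice
Title: Chromatin-State and Alternative-Splicing Consequences of Chromatin
    Remodeler Knockdown
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative epigenomics pipeline linking loss of a chromatin
    remodeler to depletion of H3K36me3 over gene bodies and to downstream
    alternative-splicing change. Provides peak-set harmonization and interval
    algebra, Bernoulli-emission hidden Markov model chromatin-state
    segmentation with per-state peak-count contrasts, input-normalized
    metagene profiles with signal extraction scaling (SES) and paired Cohen's
    d effect-size statistics, negative-binomial differential binding over
    consensus peaks, percent-spliced-in (PSI) differential splicing with an
    empirical null, RNA-binding-protein motif scanning of exon flanks with
    exact false-positive-rate calibration, affinity-purification mass
    spectrometry interactor scoring against IgG controls, gene-set overlap
    statistics, and a deterministic synthetic-data generator with planted
    ground-truth effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Rcpp,
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
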