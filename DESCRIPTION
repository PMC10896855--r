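Package: atacdar
Title: Differential Chromatin Accessibility at cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying injury-responsive cis-regulatory
    elements from multi-omic assays of sensory-neuron tissue. Converts aligned
    ATAC-seq fragments into Tn5 insertion events with the +4/-5 footprint
    correction, builds binned coverage, group-average and difference tracks,
    calls peaks with a simplified Poisson caller, constructs an
    H3K4me1-constrained reproducible consensus region set, tests differential
    accessibility between groups with a negative-binomial Wald test, annotates
    regions by genomic feature and nearest transcription start site, integrates
    RNA-seq differential expression for direction concordance, performs
    known-motif enrichment with exact position-weight-matrix score thresholds,
    and scores transcription-factor protein microarrays with locally normalized
    Z-scores and an all-four-spots hit rule. A synthetic-data module generates
    every pipeline input with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
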