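Package: ampliCall
Title: Low-Prevalence Variant Detection in Ultra-Deep Targeted Amplicon
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects somatic single-nucleotide variants at prevalences down
    to 1% in ultra-deep targeted amplicon sequencing data. A calibration
    sample with known variant prevalences, sequenced in the same run, is
    used to train an empirical sequencing-error model stratified by read
    direction, read position and substitution type, with depth-weighted
    smoothing across read positions. Candidate positions are screened by
    a set of prefilters, tested per direction with a binomial tail test
    against the modelled error rate, combined across directions by a
    depth-weighted Stouffer Z-score, and thresholded at the p-value that
    maximizes the Matthews correlation coefficient on the calibration
    truth set. Includes tumor/germline somatic classification, masking of
    recurrently noisy positions from control samples, a cross-species
    (xenograft host genome) mismatch filter, a calibration-pool pileup
    simulator with stratified error profiles, and performance evaluation
    over calibration permutations and coverage-downsampling ladders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
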