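Package: cfCNA
Title: Shallow Whole-Genome Sequencing Analysis of Cell-Free DNA Copy Number
Version: 0.1.0
Authors@R: person("cfCNA", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and quantification of circulating tumor DNA from
    shallow whole-genome sequencing of plasma cell-free DNA. Provides genome
    binning (fixed-width and equal-mappable-base schemes), GC-bias correction
    and panel-of-normals depth normalization, circular binary segmentation,
    a restricted-state hidden Markov model for tumor-fraction inference,
    cohort recurrence scoring with permutation significance, fragment-size
    profiling with nucleosome-periodicity detection, rank-based cohort
    statistics with ROC analysis, and a fully seeded synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
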