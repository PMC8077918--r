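Package: wgscohort
Title: Tumor-Normal Whole-Genome Cohort Comparison Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and statistical toolkit for comparing
    tumor/normal whole-genome sequencing cohorts. Implements read-depth
    based somatic copy-number segmentation (normalization, 3-kb binning,
    sliding-median smoothing, constant-region segmentation, gain/loss
    classification), 1-Mb binned cohort frequency maps with per-bin Fisher
    comparison and a label-randomization null, loss-of-heterozygosity
    calling from paired genotypes, clonal-architecture metrics (MATH score,
    binomial-mixture clone-count estimation, evolutionary-tree topology
    classification), trinucleotide mutation spectra with non-negative
    signature-weight fitting, and parsimonious (lowest-common-ancestor)
    taxonomic assignment of candidate exogenous reads. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
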