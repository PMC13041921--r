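Package: satarch
Title: Satellite DNA and Acrocentric Chromosome Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the repeat architecture of primate
    centromeres and acrocentric short arms. Implements k-mer interval
    periodicity spectra for tandem repeat detection, monomer segmentation
    and consensus building, higher-order repeat detection, profile-based
    alpha-satellite family classification with array-level annotation,
    dimer haplotype calling and chromosome-specific k-mer signatures,
    pseudo-homologous region (PHR) detection between heterologous arms,
    self-identity matrices, and ribosomal DNA array analysis (unit
    detection, depth-based copy-number estimation, per-array copy
    allocation, methylation-based activity classification, centromere
    dip region calling, and sex comparison of copy numbers). A synthetic
    genome generator with planted ground truth makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
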