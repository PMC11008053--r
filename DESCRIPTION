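Package: clonetrace
Title: Single-Cell Expressed-Barcode Lineage Tracing of Drug-Resistant Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clonal dynamics of drug resistance with
    expressed DNA barcodes in single-cell RNA-seq. Recovers lineage
    barcodes (bc14:TGGT:bc30 cassettes) from raw paired reads with
    whitelist Hamming-1 error correction, performs cell- and gene-level
    quality control (UMI depth, loess mitochondrial and doublet filters),
    runs retrospective (tolerant vs sensitive) and prospective
    (dominant vs neutral) clone analyses with rank-sum marker testing and
    clone-frequency dominance calls, fits a supervised ordinal-regression
    pseudotime with rolling-median binning and spline time-course
    differential testing, and trains a contrastive autoencoder plus
    cosine-kernel SVM classifier of per-cell drug response with
    permutation feature importance and random-panel benchmarking. A
    synthetic-data generator emulates a barcoded cell population under
    drug selection end-to-end, down to FASTQ reads, with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    e1071,
    Rcpp,
    jsonlite,
    methods,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
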