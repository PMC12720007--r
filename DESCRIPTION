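Package: telopeaks
Title: Telomeric Repeat Content and Overlap Analysis of Genomic Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether two sets of genomic peaks - such as
    lncRNA chromatin-occupancy peaks and R-loop peaks - co-locate more often
    than expected by chance, and whether the co-located peaks are
    distinguished by their tandem telomeric repeat content. Implements
    BED-family input/output, minimum-one-base-pair intersection partitioning
    of two peak sets into shared and unique peaks, exact telomeric hexamer
    (TTAGGG/CCCTAA) scanning with tandem-run detection and a five-class
    repeat-content classification, a constrained permutation test of overlap
    significance that preserves peak number, size and chromosome
    distribution, midpoint-based genomic annotation against BED12 gene
    models, the headline repeat-content summary statistics, and a
    synthetic-fixture generator that plants telomeric arrays and designed
    peak overlaps with a machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
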