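Package: clonecheck
Title: Genomic Integrity and Provenance Checks for Immortalized Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to establish the provenance and genomic integrity of
    cultured cell lines from long-read sequencing and simple bench assays:
    coverage-peak estimation of mosaic chromosome copy number and genetic sex
    from binned read depth, proviral integration-site mapping from
    vector-containing reads via k-mer flank anchoring, CRISPR amplicon indel
    quantification with global affine-gap alignment and knockout clone
    classification, and log-phase doubling-time estimation from timed cell
    counts. A synthetic-data module simulates mosaic aneuploid populations,
    proviral insertions, edited amplicon read sets and exponential growth
    counts with known ground truth, so every stage is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
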