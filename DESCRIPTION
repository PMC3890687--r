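Package: barcodegap
Title: Barcode Gap Analysis, Distance Thresholds and Molecular Species
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for DNA barcoding markers in taxa where
    universal primers underperform, such as monogenean and rhabdocoel
    flatworms. Computes Kimura two-parameter (K2P) pairwise distances with
    pairwise deletion, partitions them into intra- and interspecific sets,
    detects the barcode gap, estimates the best compromise threshold (BCTh)
    from cumulative error curves, and scores species identification success
    under the best match (BM) and best close-match (BCM) criteria. Also
    screens cloned amplicons for contamination by assigning them to taxon
    groups with a labeled reference panel, using both nearest-reference
    distances and neighbour-joining clade membership, and ships a K2P
    sequence simulator with controllable intra/interspecific divergence,
    singletons, shared haplotypes and contaminant admixture for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
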