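Package: chipcooc
Title: Integrative Co-Occupancy Analysis of ChIP-Seq Peak Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic integration of transcription-factor ChIP-seq peak
    sets across experiments, cell types and species. Builds merged-region by
    experiment binary occupancy matrices, clusters correlation heatmaps with
    optimal leaf ordering, profiles TSS-proximity preferences of factors,
    characterises promoter-proximal versus distal transcription-factor
    binding hotspots by k-means on TF density, scores exact combinatorial
    binding patterns against marginal-preserving randomizations, and tests
    peak sets for enrichment of GWAS disease-associated loci with a
    Bonferroni-corrected hypergeometric test. Includes a synthetic peak-set
    simulator with planted ground truth for end-to-end validation, and a
    staged pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
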