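Package: cdegscreen
Title: Cross-Species Conserved Signatures and Connectivity-Map Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico drug-repositioning pipeline for two-species disease
    models. Derives differentially expressed genes per species with a moderated
    t-statistic, maps mouse symbols onto human orthologs, extracts the
    direction-concordant conserved signature (cDEG) and tests its overlap
    significance, screens the signature against a ranked perturbagen reference
    with the rank-based Kolmogorov-Smirnov connectivity score to find
    signature-reversing molecules, runs preranked gene-set enrichment and
    over-representation analyses, triages hits with a bibliometric score, and
    renders the cell-line bubble plot. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
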