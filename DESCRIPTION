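Package: emtscape
Title: EMT Signature Scoring and Immune Landscape Analysis for Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample epithelial-mesenchymal transition (EMT)
    scores from a 16-gene marker signature on RNA-seq z-score matrices,
    stratifies cohorts into mesenchymal/epithelial tertiles, calls per-sample
    immune cell infiltration from metagene signatures with a single-sample
    weighted Kolmogorov-Smirnov enrichment statistic, a gene-label
    permutation null and Benjamini-Hochberg false discovery control, and
    contrasts infiltration fractions, cytokine and immune checkpoint
    expression, and overall survival between EMT groups. Includes a
    synthetic-cohort generator with planted ground truth so the whole
    pipeline is testable without access to tumor expression data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
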