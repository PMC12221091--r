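Package: settleprot
Title: Time-Course Proteomics of Zoospore Settlement in Thraustochytrids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative time-course proteomics of the
    zoospore-to-vegetative-cell transition in thraustochytrids such as
    Aurantiochytrium limacinum. Merges two predicted-proteome identifier
    spaces by reciprocal best hits, applies generalized-log variance
    stabilization and empirical-Bayes batch correction, computes moderated
    t-statistics for each post-settlement timepoint against the zoospore
    reference, clusters temporal profiles by k-means under Pearson distance,
    tests functional-term enrichment with exact hypergeometric tails, and
    screens for taxonomically restricted upregulated proteins (candidate
    ectoplasmic-network/bothrosome components) via homology-hit
    classification and orthogroup filtering. A synthetic-data module
    generates every pipeline input with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
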