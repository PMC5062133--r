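Package: miRQ
Title: Prioritization of Cancer-Related microRNAs by Order-Statistics
    Rank Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate cancer-related microRNAs from paired
    miRNA/mRNA tumor expression matrices and predicted-target tables.
    Three per-miRNA features (mean tumor expression, mean absolute
    Pearson correlation with all genes, and predicted target count) are
    integrated with a bidirectional order-statistics Q ranking. Includes
    evaluation against disease-annotation lists (cumulative annotation
    ratios, hypergeometric overlap tests), per-miRNA pathway enrichment
    with Benjamini-Hochberg correction, Kaplan-Meier survival
    stratification by expression extremes, and a synthetic paired-data
    generator with planted driver miRNAs for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
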