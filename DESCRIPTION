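Package: methmark
Title: Multi-Cancer DNA Methylation Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("methmark", "developers", email = "methmark@example.org",
           role = c("aut", "cre"))
Description: Discovery of pan-cancer DNA methylation biomarker panels from
    Illumina 450K-style beta-value matrices. Implements probe-level
    differential methylation calling with interquartile-range outlier
    removal and Benjamini-Hochberg correction, intersection with
    comorbidity-derived gene sets, cross-cancer common-biomarker selection,
    a Gene Ontology functional gene distance combining information-content
    and Sorensen-Dice components, UPGMA functional grouping, and SVM-based
    selection of the optimal one-marker-per-group panel. Ships a synthetic
    data generator with planted ground truth so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
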