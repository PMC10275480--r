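Package: paradiv
Title: Transcriptional and Translational Divergence of Paralogous Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how much of the expression divergence within
    paralogous gene pairs occurred in transcription versus translation,
    starting from molecular transcription rates (mRNA per hour) and
    translation rates (proteins per mRNA per hour), and simulates
    post-duplication expression evolution by sequential fixation under a
    minimal quantitative-subfunctionalization model and a
    precision-economy variant that prices expression noise and
    transcription cost into fitness.  Includes fold-change and
    rank-correlation divergence statistics with bootstrap intervals,
    Monte-Carlo studies of measurement noise and of spurious correlations
    induced by shared mRNA measurements, mutation models with skewed or
    correlated transcriptional and translational effects, grid-search
    calibration of mutational parameters against reference divergence
    patterns, and generators for synthetic rate tables emulating the
    statistical structure of the budding-yeast dataset the analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
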