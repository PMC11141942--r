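Package: chronotarget
Title: Circadian Transcriptome Analysis and Chronotherapy Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rhythmic genes in short temporal expression series using
    three periodicity statistics (cosinor harmonic regression, a JTK-style
    rank-concordance test with exact small-sample null, and the Lomb-Scargle
    periodogram) integrated by Fisher's method with Benjamini-Hochberg FDR
    control; scores protein-interaction networks with twelve topology
    parameters and calls consensus hub genes; quantifies coupling between
    candidate genes and the core circadian clock panel; performs
    hypergeometric gene-set overrepresentation tests; fits four-parameter
    logistic dose-response curves to relate time-of-day drug efficacy to
    rhythmic target expression; and prioritizes chronotherapy targets.
    Includes a seeded synthetic-data generator producing temporal expression
    matrices, planted-hub interaction networks, and phase-modulated viability
    panels with ground-truth tables for recovery benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
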