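Package: txfingerprint
Title: Blood Transcriptome Module Repertoire Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group-level analysis of case/control blood transcriptome
    cohorts against a fixed repertoire of co-expressed transcriptional
    modules. Computes per-transcript direction calls (Welch or Student t,
    or Wilcoxon, with in-house Benjamini-Hochberg correction), summarises
    each module as a signed percent-response with dominant-trend
    retention, assembles fixed-position fingerprint grids and
    cross-cohort fingerprint matrices, forms module aggregates by
    hierarchical clustering of response patterns, and renders fingerprint
    grid plots and clustered heatmaps. Includes a synthetic-cohort
    generator with planted module effects so the full pipeline is
    testable without external data, plus a packaged fixture describing
    the 21 inflammation-associated modules of aggregate A35.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
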