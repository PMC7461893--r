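Package: semkos
Title: Semi-Automatic Knowledge Organization Systems from Biomedical Full Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hierarchical knowledge organization systems (KOS) from
    full-text biomedical article collections. Reads JATS/NXML articles,
    extracts author keywords and method names from methods-section subtitles,
    recognizes multiword terms by longest-phrase-first matching, trains joint
    term and document embeddings, organizes terms into a binary average-linkage
    (UPGMA) merge tree with branch-review sampling for manual curation,
    computes citation-weighted keyword-by-method co-occurrence matrices with
    power-law diagnostics, and profiles article groups through coverage
    vectors and multi-round affinity-propagation clustering. Includes a
    planted-structure synthetic corpus generator for end-to-end validation
    and a pipeline runner with stage caching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    ape,
    mclust,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
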