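Package: sketchoverlap
Title: MinHash Sketching for Protein Family Overlap Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares candidate protein families against a database of existing
    families in sub-second time using bottom-n MinHash sketches of residue-level
    region sets. Families are represented as sets of (protein, residue-chunk)
    elements; the package estimates both the Jaccard index and the asymmetric
    Jaccard containment between a query and every indexed family, and classifies
    the query as novel, overlapping a single family (possibly as a superior
    model with increased residue coverage), or overlapping multiple families
    within or across clans. Includes exact set-arithmetic oracles, a seeded
    synthetic region-set generator with planted overlap relationships, index
    persistence, and a command-line interface with a benchmark harness.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
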