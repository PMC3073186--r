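Package: gramtriple
Title: Selective N-Gram Indexing for Regular-Expression SPARQL Queries over RDF Triples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory RDF triple store with per-part (subject, predicate,
    object) inverted indexes over selective n-grams, a compiler that turns
    regular-expression FILTER patterns into candidate-generation plans over
    those indexes (index scans combined with offset-aware intersections and
    unions), a candidate-then-verify execution engine following the GetNext
    iterator model, and a page-access cost model that selects query execution
    plans for a restricted SPARQL subset. Includes a seeded generator of
    GeneOntology-like synthetic N-Triples corpora and brute-force oracles for
    property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
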