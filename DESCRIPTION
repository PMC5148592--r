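Package: ehraql
Title: Archetype Containment Queries over Structured Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data access layer for large collections of deeply nested,
    heterogeneous structured biomedical records modelled after the openEHR
    two-level approach.  Records are document trees whose nodes are archetype
    instances; an index service canonicalises each record's value-free
    archetype skeleton, assigns it a content-derived identifier and resolves
    AQL containment chains to (structure, path) matches so that queries touch
    only records whose structure can satisfy the FROM clause.  Includes an
    AQL subset parser, an interchangeable storage-driver layer with an
    embedded reference driver supporting versioning and rollback, a serial
    index-free recursive scanner used as a correctness oracle, a seeded
    synthetic-corpus generator with planted ground truth, and a benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
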