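Package: phenovset
Title: Intensional and Extensional Value Sets over Clinical Concept Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, expanding and auditing SNOMED CT-style
    value sets that define computable clinical phenotypes. Represents
    rule-based (intensional) value sets in a small subset of the
    Expression Constraint Language, expands them over an is-a concept
    polyhierarchy into exactly-equivalent enumerated (extensional) sets,
    and compares rule-based against list-based definitions on
    conciseness (concepts needed to define), creation time (a linear
    cost model), and completeness (concept- and clinical-term-level
    coverage), with median-based summary tables. Includes a synthetic
    ontology and term-map generator so the whole pipeline can be
    exercised without a licensed terminology release, and readers and
    writers for RF2 snapshot tables, edge tables, term maps and
    VSAC-style export CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
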