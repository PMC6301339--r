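Package: annotriage
Title: Literature Triage and Ontology-Concept Annotation Support for Biocuration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation-support toolkit for gene-centric literature annotation.
    Ranks MEDLINE-style abstracts for a (gene, annotation-axis) query with a
    linear combination of Okapi BM25, ontology-concept range and TF-IDF scores;
    extracts Gene Ontology biological-process and disease-terminology concepts
    by dictionary matching with exact character offsets; proposes ranked
    annotation triplets (subject, relation, concept object, evidence code) with
    blacklist filtering and accept/modify/reject review semantics; and
    evaluates the whole pipeline with triage precision, inter-annotator
    agreement, class-level concept precision/recall, per-term rejection tables,
    precision-at-rank and relative gain. Ships a deterministic synthetic-data
    generator (mini-ontologies, planted-signal corpora, simulated dual-curator
    judgments) so every stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
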