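Package: pddikit
Title: Annotation, Preannotation, and Agreement Analysis for
    Pharmacokinetic Drug-Drug Interaction Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating annotated corpora of
    pharmacokinetic drug-drug interaction (PDDI) mentions in drug product
    label sections.  Provides a typed annotation data model with
    Open-Annotation-style JSON interchange, deterministic sentence
    segmentation, dictionary-based drug named-entity recognition with
    product-to-ingredient normalization, a transparent rule-based
    sentence-level PDDI extractor for NLP preannotation, span-overlap
    matching with per-label precision/recall/F1 macro-averaged by
    scenario, three-way user/NLP/reference agreement cross-tabulations,
    length-balanced scenario assignment, and a synthetic corpus and
    annotator simulator with configurable error rates for end-to-end
    evaluation without human participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
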