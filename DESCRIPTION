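Package: anatag
Title: Anatomical Entity Mention Recognition with Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A retrainable sequence-labeling system for recognizing and
    typing anatomical entity mentions in biomedical text.  Implements the
    full feature-engineering pipeline around a linear-chain conditional
    random field: aggressive tokenization and rule-based sentence
    segmentation, unigram-model truecasing, dictionary features compiled
    from OBO ontologies and from string-to-type occurrence records
    (majority filtering), hierarchical Brown-cluster prefix features,
    document-level non-local features with two-stage tagging, additive
    label-bias decoding, and mention-level evaluation with right-boundary
    or exact matching.  Includes a synthetic-corpus generator so every
    pipeline stage can be exercised without external resources, plus
    readers and writers for BioNLP-style standoff annotation and
    CoNLL-style TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
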