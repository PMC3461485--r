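Package: semsumm
Title: Dynamic Summarization of Biomedical Semantic Predications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-of-view summarization of subject-predicate-object
    assertions (semantic predications) extracted from biomedical citation
    text. Implements a four-tier filter cascade (Relevance, Connectivity,
    Novelty, Saliency) whose saliency stage scores semantic-type/predicate
    patterns by the product of a Kullback-Leibler predicate-enrichment term,
    an RlogF pattern-relevance term, and a PredScal scaling factor. Also
    provides a term-frequency baseline summarizer (mean plus one standard
    deviation threshold), an evaluation harness (recall, precision, F1,
    inter-annotator agreement) against reference-standard intervention
    lists, and a synthetic corpus generator with planted enriched patterns
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
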