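Package: combosum
Title: Dynamic Summarization of Semantic Predications with the Combo Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks subject-predicate-object assertions (semantic predications)
    extracted from biomedical literature by a composite statistic that combines
    per-predicate Kullback-Leibler divergence between a query-focused foreground
    corpus and a topic-wide background corpus, the RlogF semantic-type binding
    strength, and a PredScal vocabulary-size scaling factor. Implements the
    four-filter summarization pipeline (relevance, connectivity, novelty,
    saliency) with single-metric comparison arms, a gene-curation evaluation
    protocol with recall, precision and F, a synthetic predication-corpus
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
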