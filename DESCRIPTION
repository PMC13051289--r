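Package: subtypebench
Title: Benchmark Machinery for Tweet-Level Depression-Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline components for benchmarking six-class
    depression-subtype classification of short social-media posts: corpus
    input/output with deduplication and stratified splitting, a seeded
    generator of tweet-like corpora with controllable cross-class lexical
    overlap, a composite imbalance-aware training objective (class-balanced
    focal loss with label-distribution-aware margins, R-Drop consistency,
    and a targeted pairwise margin penalty), a few-shot multiple-choice
    prompting protocol with self-consistency voting, a LoRA fine-tuning
    regimen expressed against an abstract encoder contract with a desk-scale
    fixture implementation, and a shared evaluation layer (macro-F1,
    per-class metrics, confusion matrices, model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
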