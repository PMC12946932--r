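Package: phqscreen
Title: PHQ-9 Depression Screening from Free Text with SNOMED CT Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that screens free-text posts for
    depressive symptoms. A symptom ontology detects PHQ-9 cue phrases with
    temporal frequency modifiers, a deterministic feature-hashed sentence
    embedder feeds a small feedforward softmax classifier that assigns
    sentences to PHQ-9 items under a confidence threshold, and the resulting
    yes/no checklist is scored into the standard PHQ-9 severity bands. The
    diagnosis label is then normalized to the closest SNOMED CT concept by
    keyword filtering of an RF2-style description table followed by
    cosine-similarity reranking, and a deterministic template engine renders
    clinician-readable explanations. Includes confusion-matrix evaluation
    metrics and a seeded synthetic-corpus generator emulating binary
    PHQ-9 item annotations so the whole pipeline trains and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
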