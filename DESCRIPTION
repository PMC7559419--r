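Package: emovolve
Title: Event-Driven Tracking of Public Emotion Evolution on Microblogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Lexicon-based analysis of how fine-grained public emotions evolve
    on microblogging platforms over the course of an epidemic. Scores daily
    documents against a degree-weighted affective vocabulary (seven emotion
    categories, 21 sub-emotions) using term frequency-inverse document
    frequency weighting, extracts the epidemic skeleton (new and accumulated
    confirmed cases) from post text, segments the timeline into phases at
    change points of the new-case series, and quantifies phase-wise emotion
    covariance, rank-based emotion transitions, and rank-fusion trending-event
    scores. Includes a fully seeded synthetic corpus generator so every stage
    of the pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
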