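Package: cuscore
Title: Content-Unit Scoring and Informativeness of Picture-Description Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the informativeness of naturalistic speech
    elicited by picture-description tasks, aimed at clinical speech-language
    research in primary progressive aphasia (PPA). Implements content-unit (CU)
    scoring of transcripts against a packaged 64-concept lexicon under two
    coding schemes (classic de-duplicated CU counts and a unique-referent
    refinement), a normalized informativeness statistic (raw CUs per
    utterance), word-level classification of five atypical speech categories
    (self-referential, inability, tangential, empty, false starts), group-level
    statistics (one-way ANOVA from raw data or summary statistics,
    Bonferroni-corrected pairwise t-tests, Hedges' g, normal-range impairment
    flags), and a seeded synthetic-cohort generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
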