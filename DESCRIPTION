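Package: melopredict
Title: Variable-Order Markov Models of Melodic Expectation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical models of melodic expectation based on variable-order
    Markov (PPM-style) prediction over multiple melodic viewpoints, with
    long-term (corpus-trained) and short-term (online, per-piece) models
    combined by entropy weighting.  Provides per-note information-content and
    entropy profiles, compression-distance melodic similarity, detection of
    phrase boundaries at peaks of unexpectedness, empirical-Bayes metrical
    inference from note onsets, and a two-culture analysis of musical
    enculturation (within- and between-culture information content, cultural
    distance and culture-neutral complexity, minimum-information-content
    classification).  Reads monophonic melodies from **kern, EsAC, Standard
    MIDI File and a plain tabular format, and includes seeded generators of
    synthetic corpora with known Markov structure for model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
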