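Package: emovar
Title: Emotional Variance Analysis of Sentence-Level Sentiment in Journal Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lexicon-based, valence-shifter-aware sentence sentiment scoring
    together with a set of 21 engineered features (42 in filtered and
    unfiltered variants) that summarise emotional variability across a
    document: sentiment islands, sign flips, peaks, smoothness, and
    dispersion statistics. Includes a multilayer perceptron regression
    pipeline with K-fold cross-validation for predicting numeric performance
    scores from the feature vectors, a synthetic-corpus generator with
    planted ground truth for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
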