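Package: chatmood
Title: Analysis of Depressive-Mood Discourse in Chatbot Conversation Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how users express depressive and sad moods in
    open-domain chatbot conversation logs. Provides keyword-based corpus
    construction with region mapping and PII masking, dictionary-based
    psycholinguistic word-category scoring with Welch t-tests, top-k n-gram and
    diurnal chat-frequency analysis, inter-rater agreement (Fleiss kappa) and
    consensus filtering for annotated subsets, a bag-of-words / part-of-speech /
    sentence-embedding feature stack, a semisupervised self-training classifier
    over eight depressive-discourse categories with high-confidence evaluation,
    and contingency-table comparison of category distributions across regions
    and platforms. A seeded synthetic chat-log generator reproduces the
    statistical structure the analyses assume, so the full pipeline is testable
    without access to proprietary chat data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nnet,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
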