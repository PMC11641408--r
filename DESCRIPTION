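Package: fluortweet
Title: Content Analysis of Topical-Fluoride Posts from Short-Message Corpora
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for mining public perception of topical
    fluoride treatments from short social-media posts. Implements keyword
    filtering, tweet tokenization, near-duplicate elimination by word-level
    Levenshtein distance with greedy leader clustering, expert-seeded
    nearest-neighbour categorization into concern/experience/positive/negative
    content classes, inter-rater agreement (percent agreement and Cohen's
    kappa), Wald-Wolfowitz runs tests for quarterly trends, chi-square tests
    for gender differences, and term/hashtag frequency tables. Includes a
    synthetic-corpus generator with full ground truth (latent categories,
    retweet and advertisement clusters, author multiplicity, gender
    attributes, quarterly volume trends) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
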