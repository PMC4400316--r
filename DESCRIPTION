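Package: painstream
Title: Text, Sentiment, and Community Structure Analysis of Pain-Related Microblog Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining short microblog posts ("tweets") that mention an
    emotive query term such as "pain": corpus ingestion and reduction
    (deduplication, tokenization with negation-aware stopwords, timestamp
    localization), a hybrid sentiment classifier combining a weighted-lexicon
    rule scorer with negation reversal and a multinomial Naive Bayes model with
    risk-ratio feature selection, term co-occurrence graphs with a from-scratch
    Louvain modularity community detection, geo-temporal sentiment aggregation
    with homogeneity tests and Spearman correlations against city covariates,
    and directed retweet/mention network topology metrics. A synthetic tweet
    generator with full ground truth replaces undeposited social-media corpora
    so that every stage is testable end to end without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
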