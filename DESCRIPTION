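Package: ontarget
Title: Drug Target-Group Prediction from Ontology Term Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the target-protein group of a drug from its chemical
    ontology annotations. An OBO ontology is parsed into an undirected term
    graph; compound pairs are scored by the mean shortest-path hop distance
    between their ontology term sets; a query drug is classified by majority
    vote among the training drugs at the exact minimum distance, with seeded
    random tie-breaking. A chemical-chemical interaction-score variant
    (maximum STITCH-style combined score) is included as a comparison
    predictor, along with jackknife (leave-one-out) and independent-test
    evaluation, benchmark filtering rules, and a synthetic benchmark
    generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
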