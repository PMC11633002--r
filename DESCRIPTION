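Package: splicecor
Title: Splicing-Aware Analysis of Gene-Gene Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for splicing-induced inter-sample variation in gene-gene
    total-expression correlations from bulk RNA-seq. Fits a linear
    mixed-effects model in which the slope between two genes' expression
    levels varies across samples with covariance proportional to the
    sample-sample similarity of the predictor gene's intron-excision-ratio
    (isoform composition) profile. Provides a variance-component score test
    for the interaction (random-slope) component with mixture-of-chi-square
    p-values (Liu moment matching and exact numerical inversion), a joint
    fixed-plus-random association test combined over a grid of
    variance-partition values, multiple-testing utilities (Benjamini-
    Hochberg, stratified FDR, Storey's pi0), directed co-expression network
    summaries, and a generative simulator emulating expression,
    intron-excision-ratio and covariate inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
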