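Package: ampliconrep
Title: Reproducibility Analysis for Amplicon Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how PCR-replicate pooling, sequencing
    depth and sequencing platform affect ecological inference from amplicon
    OTU tables. Provides alpha-diversity estimators (observed richness,
    Chao1, Fisher's alpha, Simpson, Simpson evenness) with seeded
    rarefaction, beta-diversity dissimilarities (Bray-Curtis, binary
    Jaccard, beta-sim), pseudo-beta-diversity depth curves between
    technical replicates, per-OTU detection-frequency analysis with a
    binomial logistic model, replicate abundance concordance, factorial
    ANOVA, Mantel and perMANOVA permutation tests, cross-platform OTU
    overlap accounting, and a stochastic library-preparation simulator
    (template sampling, per-taxon PCR efficiency, replicate pooling,
    platform-specific sequencing depth and spurious-OTU error) that
    emulates a pooled-PCR replication study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
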