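Package: mztwin
Title: Microbiome-Based Identification of Monozygotic Twins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for distinguishing monozygotic twins from their own
    repeated samples using microbial community profiles (16S rRNA ASV or
    OTU count tables). Implements rare-feature filtering, within-twin-pair
    sample pair enumeration with stratified train/test splits, masked
    beta-diversity distances (Jaccard, Bray-Curtis, Hellinger), a rank-based
    AUC with mid-rank tie handling, genetic-algorithm feature selection
    maximizing that AUC, Gaussian kernel density estimation of group-wise
    distance distributions, likelihood-ratio evidence evaluation with
    Youden-index threshold selection, alpha-diversity estimators (Chao 1,
    ACE, Shannon, Simpson) with paired inner-individual comparisons, and a
    twin-cohort simulator with ground-truth feature labels for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
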