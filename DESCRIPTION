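Package: replitimer
Title: Replication Timing, Chromatin Feature Attribution, and Okazaki
    Fragment Strand Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit linking DNA replication timing (RT) to the
    local chromatin state and to replication origin activity. Turns binned
    early/late S-phase Repli-seq counts into loess-smoothed log2 RT tracks
    with per-bin differential statistics, partitions RT and delta-RT tracks
    into domains by circular binary segmentation, builds segment-by-feature
    matrices of background-corrected peak signal and fits elastic-net models
    attributing RT to chromatin features, and computes Okazaki-fragment
    (OK-seq) replication fork directionality, strand-bias metagenes around
    stratified reference points and the associated rank tests. Ships a
    seeded synthetic-data generator with known ground truth (latent RT
    landscape, causal feature weights, origin efficiencies) on which every
    stage of the pipeline is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
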