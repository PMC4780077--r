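Package: mocha
Title: Modulation of Transcriptional Regulation via Chromatin Activity
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies chromatin regulators (CRs) that modulate
    transcription-factor to target-gene regulation from gene expression
    time courses. Scores CR-TF-TG triplets by Fisher's combined
    probability test over four lines of evidence (mutual information,
    liquid association, and phenotype consistency of CR and TF), infers a
    latent per-region chromatin activity with a linear-Gaussian Bayesian
    network fitted by hard-assignment EM, and builds a CR-CR
    combinational-modulation network with degree-preserving permutation
    nulls. Includes a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
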