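Package: doubletcode
Title: Temporal Coding by Spike Doublets in Sensory Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for temporal encoding by short spike doublets
    in sensory interneurons driven by band-limited Gaussian white-noise
    stimuli. Provides interspike-interval statistics and refractory
    recovery-function fitting, repeatable-event detection in frozen-noise
    rasters with onset-jitter and within-doublet correlation fits, three
    doublet timing-variability models with conditional-entropy and
    information-rate calculations, direct (context-tree weighting) and
    linear (multitaper coherence) information estimates, pattern-conditioned
    Gaussian stimulus models with synthetic doublet-model construction and
    cross-validated log-likelihood-ratio tests, and an information-theoretic
    spike-triggered (iSTAC) subspace analysis of where linear predictions
    fail. A synthetic-data module generates surrogate stimuli and spike
    trains with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
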