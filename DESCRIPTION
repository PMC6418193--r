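Package: promlock
Title: Stochastic Modelling of Supercoiling-Mediated Promoter Locking in
    Bacterial Transcription
Version: 0.1.0
Authors@R:
    person("Biosystem", "Dynamics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how DNA supercoiling buildup can trap a
    chromosome-integrated bacterial promoter in transcriptionally inactive
    ("locked") states. Provides a delayed stochastic simulation engine for a
    transcription initiation model with closed-complex kinetics, repressor
    switching and promoter locking; a population simulation protocol with
    relative-trajectory normalization and a one-dimensional scan of the
    unlocking rate; single-cell RNA-count statistics (mean, squared
    coefficient of variation, Kolmogorov-Smirnov comparisons, Student-t
    confidence intervals); a Lineweaver-Burk decomposition of the mean
    inter-transcription interval into fractions before and after commitment
    to open complex formation; a bootstrap enrichment analysis of cold-shock
    gene sets against genome-wide supercoiling sensitivity; and synthetic
    data generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
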