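Package: otupln
Title: Quantitative Metabarcoding with Poisson-Lognormal Mixed Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based analysis of amplicon OTU count tables. Fits a
    Poisson-lognormal generalized linear mixed model to sample-by-OTU
    counts jointly with an artificial "sum-OTU" that carries each
    sample's total, so that OTU effects can be expressed relative to
    total coverage and systematic coverage biases cancel in contrasts.
    Includes Bayesian MCMC fitting with posterior pairwise contrasts
    and false-discovery-rate correction, screening rules for outlier
    samples and quantifiable OTUs, depth normalisation with started-log
    and log-linear hybrid transforms, PCA preparation, paralog
    detection via abundance correlations, a simplified reads-to-counts
    pipeline (quality filtering, greedy centroid clustering,
    unambiguous read mapping), and a synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
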