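Package: dyadseq
Title: Statistical Models for Paired Behavioral Sequences from Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing interval-sampled observational data from
    dyads (e.g., couples): two interdependent binary behavior streams per
    dyad are joined into a four-state sequence and analyzed with descriptive
    sequence statistics (state-distribution, Shannon entropy, transition
    counts), per-dyad saturated effect-coded logit models aggregated into an
    actor-partner interdependence model, a dyadic multilevel logistic model,
    basic, hidden, and mixture Markov models estimated by EM, optimal-matching
    sequence dissimilarities with transition-rate substitution costs followed
    by Ward clustering and silhouette-based selection, and study-design
    helpers (zero/low-frequency cell simulators and exact noncentral-t sample
    size calculators). Synthetic-data generators are provided for every model
    family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    ggplot2,
    lme4,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
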