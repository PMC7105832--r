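Package: raterdcm
Title: Cognitive Diagnostic Models with Rater Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulate, fit, and evaluate cognitive diagnostic models for
    rater-mediated dichotomous ratings. Implements the log-linear cognitive
    diagnosis model (LCDM) and its DINA restriction, a facets extension that
    places an additive rater-severity term inside the logit, and a
    hierarchical rater model whose signal-detection rating stage links
    observed scores to a latent ideal category governed by an LCDM.
    Estimation is by Metropolis-within-Gibbs sampling with Gelman-Rubin
    diagnostics, posterior predictive checks, and information criteria.
    Includes rating-design constructors, synthetic-data generators, and
    parameter-recovery study harnesses.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
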