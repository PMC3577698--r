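Package: cgx
Title: Bayesian Inference of Cross-Level Gene-Environment Interaction in
    Matched Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian hierarchical logistic models for matched
    case-control data in which individual SNP effects are allowed to vary
    across categories of a group-level (contextual) environmental variable.
    The across-category variance of each SNP effect quantifies cross-level
    gene-environment interaction.  Provides the full (unconditional)
    likelihood mixed-effects model with pair and area random intercepts, a
    Bayesian conditional logistic regression alternative, an adaptive
    Metropolis-within-Gibbs sampler, posterior summaries including combined
    odds ratios and heterogeneity reports, DIC model comparison, and a
    simulator for matched case-control studies nested in contextual
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
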