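Package: mixtraj
Title: Semi-Supervised Bayesian Mixture Models for Single-Cell Trajectory Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers per-cell pseudotime, lineage proportions, and branch-assignment
    probabilities from single-cell expression of a small marker-gene panel, given a
    user-supplied branching topology. Cellular differentiation is modelled as a
    K-component mixture of latent lineages in which marker genes follow switch-like
    logistic activation along the lineages they mark and transient Gaussian pulses
    elsewhere, with mean-dependent overdispersion and a zero-inflation term for
    technical dropout. Posterior inference uses a built-in No-U-Turn Hamiltonian
    Monte Carlo sampler with the discrete latents marginalized. Downstream tools
    quantify differentiation potential as the Shannon entropy of branch
    probabilities and detect branch-specific genes by Bayes-factor comparison of
    sigmoidal versus constant expression models, with marginal likelihoods
    estimated by bridge sampling. A forward simulator with ground-truth time and
    branch labels and an evaluation toolkit (rank correlations, per-branch
    precision/recall/F1, Kruskal-Wallis and Mann-Whitney U tests) make the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
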