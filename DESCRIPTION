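Package: bprsnet
Title: Regularized Partial-Correlation Networks for Ordinal Symptom Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates psychometric symptom networks from ordinal rating-scale
    data such as the 18-item Brief Psychiatric Rating Scale. Provides two-step
    maximum-likelihood polychoric correlation estimation, sparse Gaussian
    graphical model fitting by graphical lasso with extended-BIC model
    selection, partial-correlation edge weights, strength/closeness/betweenness
    centrality, spin-glass community detection by simulated annealing,
    case-dropping bootstrap stability (CS-coefficient), nonparametric bootstrap
    confidence intervals, and a permutation test for differences in centrality
    between item groups. Includes a latent-Gaussian copula generator for
    ordinal data with a known sparse block-structured partial-correlation
    network, so the full pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
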