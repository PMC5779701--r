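Package: longnet
Title: Longitudinal Regularized Partial Correlation Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of regularized partial correlation
    networks (Gaussian graphical models) from longitudinal ordinal symptom
    data such as repeated CES-D assessments. Provides two-step maximum
    likelihood polychoric, polyserial and tetrachoric correlations with
    pairwise-complete observations and positive-definite repair; graphical
    lasso estimation over a penalty path with extended BIC model selection;
    strength, betweenness and closeness centrality on weighted networks;
    nonparametric and case-dropping bootstrap routines with correlation
    stability coefficients and edge/centrality difference tests; a
    permutation-based network comparison test for paired (dependent)
    designs; cross-wave similarity measures; and a synthetic longitudinal
    ordinal data generator with known ground-truth network structure for
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
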