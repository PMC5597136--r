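Package: stabvar
Title: Stable Sparse Vector-Autoregressive Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of sparse, stable, signed gene regulatory
    networks from ordered expression data (time courses or sequences of
    perturbation experiments). Fits a first-order vector autoregression by
    least squares under an entrywise-L1 sparsity budget and a weighted
    Gershgorin-disc stability constraint, with iterative updating of the
    Gershgorin weights, penalty selection by rolling one-step-ahead mean
    square forecast error, and sign-aware evaluation of inferred edges
    against a reference network. Includes a generator of sparse stable
    ground-truth models and matching synthetic expression data, readers and
    writers for expression matrices and signed edge lists, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
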