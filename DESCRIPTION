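Package: adrgraph
Title: Heterogeneous Graph Link Prediction for Adverse Drug Event Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts unobserved drug side-effect associations by link
    prediction on a heterogeneous graph combining a bipartite
    drug/side-effect network with weighted drug-drug similarity edges.
    Implements a graph convolutional encoder with a multilayer-perceptron
    link scorer trained against sampled negative links; non-negative matrix
    factorization baselines, with and without heat diffusion of the
    association matrix along the similarity graph; five closed-form
    link-prediction indices (Adamic-Adar, resource allocation, preferential
    attachment, Katz, personalized PageRank); a repeated cross-validation
    benchmarking harness with threshold and ranking metrics and
    between-method t-tests; and a seeded generator of synthetic association
    data with planted latent-factor structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
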