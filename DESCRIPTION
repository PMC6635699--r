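Package: hyperMDA
Title: Microbe-Disease Association Prediction by Random Walk with Restart
    on a Weighted Hypergraph
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts disease-associated microbes by modelling a bipartite
    microbe-disease association table as a hypergraph in which every disease
    is a hyperedge joining its associated microbes. Vertices are weighted by
    Gaussian interaction profile (GIP) kernel similarity row sums, and a
    two-step random walk with restart is run to a stationary distribution
    whose probabilities rank candidate microbes for each disease. Includes
    global and local leave-one-out cross-validation with Mann-Whitney AUC
    and ROC curves, a planted-block synthetic data generator for fully
    reproducible testing, and delimited-text readers and writers for
    association tables and ranked predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
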