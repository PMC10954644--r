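Package: hogrc
Title: Higher-Order Granger Reservoir Computing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Node-level reservoir computing (echo-state networks) whose input
    and adjacency matrices encode higher-order neighbour structure (per-node
    sets of simplicial complexes), a greedy Granger-causality-style algorithm
    that infers that structure from multivariate time series, and closed-loop
    multi-step forecasting.  Includes fixed-step RK4 simulators for benchmark
    dynamical systems (Lorenz63, coupled Lorenz63, FitzHugh-Nagumo, Roessler
    and simplified Hodgkin-Huxley networks, higher-order Kuramoto), coupling
    network generators, observational-noise injection, and comparison drivers
    for classic reservoir computing, parallel reservoir computing and the
    higher-order framework.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, Rcpp, igraph, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate:
    'hogrc-package.R'
    'utils.R'
    'structures.R'
    'trajectory.R'
    'systems.R'
    'RcppExports.R'
    'reservoir.R'
    'inference.R'
    'evaluate.R'
    'pipeline.R'
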