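Package: isingnet
Title: Exact Attractor-Landscape Statistics of Ising Spin Networks on
    Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact Boltzmann-Gibbs statistics of binary (Ising) spin
    networks coupled through weighted structural connectivity matrices:
    streaming enumeration of all spin configurations, attractor-landscape
    entropy as a function of global coupling, exact pairwise mutual
    information and correlation, Glauber-dynamics simulation for
    cross-validation, matched-edge-count graph ensembles (regular,
    small-world, random, scale-free), maximum-likelihood power-law tail
    fitting with bootstrap goodness-of-fit, model-versus-empirical
    functional-connectivity comparison, and a synthetic modular
    connectome generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
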