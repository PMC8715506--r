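Package: allokit
Title: Allosteric Communication Analysis for Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for characterising state-dependent allostery in
    labelled molecular dynamics ensembles of a receptor, built around five
    stages: an adaptive single-state ("kinetically trapped") sampling
    controller with weight-proportional replica resampling; distance-based
    featurization (inverse closest-heavy-atom distances, C-alpha distances,
    GPCR microswitch collective variables, Kabsch superposition, RMSF);
    dimensionality reduction (PCA and metric MDS) with loading back-projection;
    supervised and unsupervised per-residue importance profiling (symmetrised
    Kullback-Leibler divergence, a multilayer perceptron classifier with
    layerwise relevance propagation, PCA importance); and dynamical network
    analysis (contact edges, fluctuation correlations, -log|C| weights,
    Girvan-Newman communities, critical nodes, Floyd-Warshall optimal and
    bounded suboptimal paths). A synthetic-data module generates toy ensembles
    with planted communities, discriminative residues and allosteric paths so
    that every stage is verifiable without real trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
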