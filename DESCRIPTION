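Package: degrootga
Title: Adaptive Genetic Algorithm for Fitting DeGroot Opinion-Diffusion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the DeGroot model of opinion diffusion on small social
    networks from ordinal opinion panels using a real-coded adaptive genetic
    algorithm. Chromosomes are row-stochastic influence-weight matrices
    constrained by the network adjacency structure; selection with elitism,
    gene swapping, blending, crossover, mutation and survival operators
    evolve the population, while control parameters (operator probabilities
    and mutation noise) adapt multiplicatively during stagnation. Includes
    bidirectional transformations between n-point ordinal scales and
    continuous opinions, a bin-weighted objective function, a synthetic-data
    generator emulating connected Erdős-Rényi networks with beta-distributed
    self-weights, and a calibration-study harness that measures parameter
    recovery and solution speed across hyperparameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
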