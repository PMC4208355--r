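Package: eqmotif
Title: Analytic Equilibrium Distributions for Biochemical Reaction Motifs
Version: 0.1.0
Authors@R: person("eqmotif", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A catalogue of analytic equilibrium (stationary) distributions for
    Markov jump-process models of biochemical reaction networks: birth-death,
    finite path, circular, glued, hypercube and ladder-shaped state spaces,
    Kirchhoff's spanning-tree (Markov chain tree) method, and product-form
    Poisson equilibria for weakly reversible deficiency-zero networks of
    chemical reaction network theory. A quasi-steady-state averaging layer
    embeds these distributions into slow-scale stochastic simulation
    (Gillespie SSA), together with an exact brute-force nullspace oracle, a
    plain-text reaction file format, a seeded fixture generator and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
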