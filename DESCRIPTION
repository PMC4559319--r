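Package: mofold
Title: Multi-Objective Inverse Folding of RNA for Multiple Target Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs RNA sequences that are simultaneously compatible with
    several target secondary structures (pseudoknots allowed) and Pareto
    optimal under user-chosen objective functions. Candidate sequences are
    sampled and repaired on the dependency graph formed by the union of all
    target base pairs, so that every individual in the population remains
    compatible with every target; the search itself is a non-dominated
    sorting genetic algorithm (NSGA-II) with compatibility-preserving point
    mutation, negative-design, positive-design and crossover operators.
    Objective functions are assembled from properties (free energies,
    ensemble free energies, structure similarities, energy barriers, GC
    content) computed by folding engines: a built-in dynamic-programming toy
    engine for hermetic testing, and adapters for ViennaRNA and other
    external programs. Includes benchmark-set generation and scoring
    utilities for multistable design evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
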