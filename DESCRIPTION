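Package: novelforge
Title: Novelty-First Discovery of Protein Domain Folds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for searching protein structure space for compact,
    globular domains that cannot be assigned to any catalogued fold family.
    Implements a composite-energy replica-exchange Markov chain Monte Carlo
    sampler over sequence space, a fold-recombining genetic algorithm with
    burial-fraction-proportional stochastic selection, an iterative
    "structure-first foldtuning" enrichment loop around a generative
    sequence model, CATH-style novelty annotation with greedy TM-score
    clustering, and inverse-folding funnel construction and classification
    as a stability heuristic. All large pretrained scoring, folding and
    search models sit behind small adapter interfaces; the package ships
    deterministic desk-scale surrogate backends so every pipeline runs end
    to end on a laptop with no external downloads. Core geometry (solvent
    accessible surface area, lattice chain growth, Kabsch superposition and
    TM-score) is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
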