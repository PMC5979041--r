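Package: ligandMSM
Title: Markov State Models and Rate Theory for Ligand Binding Kinetics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic and thermodynamic inference for protein-ligand binding
    from trajectory data: tICA dimensionality reduction, k-means
    discretization, reversible Markov state model estimation with
    implied-timescale validation, PCCA+/hidden-Markov coarse-graining into
    macrostates, mean first passage times, binding rate constants and
    standard-state free energies, activation barriers from transition path
    times, transition path theory (committors, reactive fluxes, pathway
    decomposition), umbrella sampling with WHAM free-energy profiles, and
    infrequent well-tempered metadynamics with acceleration-factor rate
    rescaling and Poisson/Kolmogorov-Smirnov reliability analysis. A
    synthetic-data module (continuous-time kinetic networks with exact
    stationary/MFPT/committor oracles, overdamped Langevin dynamics on
    analytic potentials, state-conditioned feature emissions) provides
    ground truth so that every stage is verifiable without molecular
    dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph,
    bio3d,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
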