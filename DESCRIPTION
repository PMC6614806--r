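Package: pitbind
Title: Single-Molecule Probe-Plasmid Binding Kinetics in Nanopit Confinement
Version: 0.1.0
Authors@R:
    person("pitbind", "developers", email = "pitbind@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-molecule assays of
    supercoil-induced DNA site unwinding, in which fluorescent oligonucleotide
    probes bind unwound sites on supercoiled plasmids confined to femtoliter
    glass nanopits. Provides a ground-truthed synthetic-data generator
    (pit-confined two-species Brownian motion with stochastic binding,
    rendered fluorescence videos, topoisomer gel lanes), spot detection and
    trajectory linking, MSD-based diffusion estimation, threshold
    classification of bound complexes, assembly of binding time courses, and
    weighted nonlinear fitting of the pseudo-first-order binding model
    B(t) = U0*(1 - exp(-K*t)) with K = k*(P0 - U0), together with
    solution-condition bookkeeping (ionic strength, crowder excluded volume,
    semidilute crossover) and topoisomer superhelical-density fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
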