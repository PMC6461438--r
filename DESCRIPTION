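Package: dwellfit
Title: Dwell-Time Kinetics of TALE-DNA Binding at the Single-Molecule Level
Version: 0.1.0
Authors@R: person("dwellfit", "maintainers", email = "dwellfit@example.org",
    role = c("aut", "cre"))
Description: Simulates, idealizes and fits single-molecule dwell-time
    distributions for a four-state kinetic scheme of transcription
    activator-like effector (TALE) binding to DNA. Provides an exact
    Gillespie simulator for continuous-time Markov schemes observed as a
    binary FRET or colocalization signal, two-limit hysteresis idealization
    of noisy traces, empirical dwell-time cumulative distributions, global
    deterministic (ODE-based) least-squares estimation of microscopic rate
    constants across ligand concentrations with residual-resampling
    bootstrap confidence intervals, model-independent single/double
    exponential fits with F-test intervals, and derived quantities:
    apparent affinity from the coupled equilibria and free energies of
    partly folded repeat-array conformations under a nearest-neighbor
    Ising model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
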