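Package: fretfold
Title: Folding-State Analysis of Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET (smFRET)
    experiments on nucleic-acid folding, built around the four-state
    folding pathway of RNA G-quadruplexes (ssRNA, G-hairpin, G-triplex,
    G4).  Includes a discrete-state Markov trace simulator with
    potassium-dependent folding kinetics and single-step photobleaching,
    intensity-trace quality control and FRET computation, shared
    Gaussian-emission hidden Markov model fitting with BIC state-count
    selection and Viterbi idealization, multi-peak Gaussian decomposition
    of population FRET histograms with potassium-titration and
    helicase-unwinding comparisons, transition density plots, and
    microscale thermophoresis (MST) dose-response fitting with EC50-based
    affinity ranking.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
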