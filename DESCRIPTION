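Package: palmkit
Title: Simulation and Analysis of PALM Single-Molecule Localization
    Microscopy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end tools for photoactivated localization microscopy
    (PALM) and single-molecule-tracking PALM. Simulates photoactivatable
    fluorophore photophysics (stochastic activation, exponential dark-state
    blinking, bleaching), clustered membrane point patterns, camera frame
    stacks, and state-switching Brownian trajectories; localizes emitters by
    Poisson maximum-likelihood Gaussian fitting with Mortensen precision
    estimates; corrects stage drift with fiducials; groups blink events into
    molecules and estimates the dark-state lifetime from the molecule-count
    versus allowed-dark-period curve; quantifies nanoclustering with Ripley's
    K/L/H statistics, Monte Carlo envelopes and simulation-calibrated DBSCAN;
    links localizations into trajectories with a hard displacement gate; and
    infers discrete diffusion states with a displacement hidden Markov model
    fitted by EM with BIC model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
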