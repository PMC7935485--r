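Package: ambientglu
Title: Inference of Ambient and Evoked Glutamate from AMPA-Receptor Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits unipolar brush cell (UBC) AMPA-receptor currents
    to infer the glutamate concentration time course at a giant mossy-fiber
    synapse. Implements a 13-state AMPA-receptor Markov scheme driven by a
    3D point-source glutamate diffusion transient with an ambient floor,
    least-squares fitting of simulated currents to recorded traces (control
    and transporter-block conditions), a sinusoidally frequency-modulated
    stimulus-train generator, and cycle-folded PSTH sine-fit phase analysis
    of spike timing. Includes a synthetic-data module that generates
    noisy whole-cell-like recordings and spike trains with known ground
    truth for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    signal,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
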