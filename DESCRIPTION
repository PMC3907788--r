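Package: pfcmicro
Title: Conductance-Based Prefrontal Cortex Microcircuit Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a small prefrontal-cortex microcircuit of compartmental
    conductance-based neuron models (one pyramidal class and fast-spiking,
    regular-spiking and irregular-spiking interneurons) wired with AMPA, NMDA,
    GABA-A and GABA-B synapses. Provides single-cell validation protocols,
    network construction with interneuron knock-out, input-scaling and
    projection-rewiring manipulations, a persistent-activity induction protocol
    with probability maps over synaptic-ratio grids, and a spike-train and
    spectral analysis stack (binned interspike-interval statistics,
    SPIKE-distance synchrony, discrete-time firing rates, and periodograms of
    summed synaptic currents).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
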