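Package: selnet
Title: Emergent Selectivity in Randomly Connected Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates sparse, randomly connected excitatory-inhibitory firing
    rate networks performing a pulse-frequency discrimination task, and analyses
    the emergent stimulus selectivity of the simulated populations. Provides the
    network and stimulus generators (irregular pulse trains with filtered input
    currents and iso-firing-rate amplitude calibration), a fast batched
    forward-Euler integrator, ideal-observer (ROC/AUC) single-neuron selectivity
    with permutation significance bounds, pairwise noise correlations and
    selectivity-conditioned connection statistics, linear support-vector readout
    of stimulus category from population activity with weight back-conversion,
    eigen-spectrum analysis of the network linearized about its zero-input fixed
    point, and task-transfer comparisons across frequency pairs. Results are
    returned as tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    e1071,
    nortest,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
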