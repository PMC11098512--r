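Package: photodemix
Title: Removal of Direct Photocurrent Artifacts from Optogenetic Mapping
    Recordings via Constrained Low-Rank Demixing
Version: 0.1.0
Authors@R:
    person("Photodemix", "Developers", email = "maintainer@photodemix.org",
           role = c("aut", "cre"))
Description: Separates direct photocurrent artifacts from postsynaptic
    currents (PSCs) in voltage-clamp recordings acquired during two-photon
    optogenetic synaptic connectivity mapping. The artifact is modelled as a
    low-rank nonnegative matrix underapproximation of the trial-aligned trace
    matrix, fitted by ADMM with exponential-decay (isotonic/OASIS-style)
    constraints on the temporal waveforms, a windowed first step that learns
    per-trial artifact weights while the laser is on, and a second step that
    extends the waveforms over the whole trial. Includes a full simulation
    framework (double two-state opsin photocurrents, power-scaled
    gamma-distributed artifact amplitudes, PSC trains with power-dependent
    latency, overlapping trials at short inter-stimulus intervals, and
    spatially decaying hybrid contamination fields) together with simple
    connectivity detection and scoring utilities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
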