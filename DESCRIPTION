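Package: ca3net
Title: Hippocampal CA3 Microcircuit Simulation and Information-Flow Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a hippocampal CA3 microcircuit of
    pyramidal cells, PV basket cells and OLM interneurons that generates
    theta-nested gamma oscillations, together with the analysis toolkit used to
    study it: Welch power spectral density of the model local field potential,
    band power, normalized transfer entropy on spike trains, theta-gamma
    phase-amplitude modulation index, and population synchrony (popCV).
    Includes factorial conductance-scaling sweeps over NMDAR, GABA-A receptor
    and I_h targets, inverted-U dose-response characterization, and
    seed-deterministic surrogate generators for validating every metric
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
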