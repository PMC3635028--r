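Package: albind
Title: Temporal Binding in a Conductance-Based Model of the Insect Antennal Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a scaled-down locust antennal lobe as a network of
    Hodgkin-Huxley projection neurons and local neurons coupled by fast
    nicotinic excitation, fast GABAergic inhibition and a slow
    G-protein-coupled inhibitory current, and analyses the resulting spike
    trains with multi-neuron synchrony statistics: the synchrony ratio and
    binding index for projection-neuron triplets and quadruplets, the
    symmetric difference ratio between odor-specific temporally bound
    subsets, a coincidence-detecting Kenyon-cell readout, and spike-time
    scrambling controls. Includes deterministic fixture generators with
    known correlation structure so every statistic is testable without the
    biophysical simulator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
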