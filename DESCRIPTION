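Package: daisynet
Title: Synaptic Target Analysis of Patchy Lateral Projections in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the synaptic connections formed by the
    patchy ("daisy") lateral axonal projections of superficial-layer
    pyramidal cells in relation to the cortical orientation-preference map.
    Builds orientation maps from per-condition response images, computes a
    Similarity Index between the orientation domains of a dendritic tree
    and of a bouton cluster, runs a Monte Carlo biased-random-walk null
    model of synaptic target composition in virtual neuropil, performs
    physical-disector stereology, measures postsynaptic density area and
    spine volume from serial-section contour stacks, and estimates
    conduction velocities of thin myelinated axons. Includes a synthetic
    data generator (pinwheel-rich maps, SWC morphologies, Poisson neuropil
    fields, contour stacks) and fixture tables reproducing published
    count marginals so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
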