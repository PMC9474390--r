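Package: orgephys
Title: Spike-Train and Electrical-Footprint Analysis for High-Density
    Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for high-density microelectrode array (HD-MEA)
    recordings of neuronal tissue such as human cerebral organoid slices:
    spike-triggered electrical-footprint inference and unit quality control,
    axonal action-potential conduction-velocity estimation via latency flow
    graphs, network-burst detection on multi-unit activity, spectral
    parametrization of burst-period local field potentials into aperiodic and
    oscillatory components, extracellular waveform clustering on a fuzzy
    nearest-neighbour graph with Louvain community detection, directed
    functional-connectivity inference by baseline-corrected cross-correlograms
    and by transfer entropy with jittered surrogates across time scales, and
    template-based tracking of single units across recording sessions.
    Includes a seeded synthetic HD-MEA data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
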