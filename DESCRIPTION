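Package: calcinet
Title: Calcium Imaging Activity and Functional Network Analysis with a
    Ground-Truth Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for calcium-imaging recordings of neuron-glial
    cultures: deltaF/F normalization against a rolling-percentile baseline,
    hysteresis detection of calcium oscillations with per-cell and
    culture-level activity statistics, inference of a directed functional
    connectivity graph by maximum lagged Pearson correlation (edge when
    rho > 0.3, oriented by the lag), and the five standard network parameters
    (mean correlation of all and of adjacent cells, mean connections per
    cell, percent of possible connections, mean signal propagation speed).
    Includes a synthetic calcium-dynamics simulator with a planted directed
    coupling graph, distance-proportional propagation delays, transient
    kernels and imaging noise, plus sham and hypoxia condition presets, so
    the whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
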