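Package: gcfe
Title: Gershgorin Circle Feature Extraction for Biomedical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts fixed-length epochs of biomedical recordings (neural
    spikes, EEG) into weighted visibility graphs, forms a modified weighted
    Laplacian whose diagonal carries unweighted node degrees, and summarises
    each epoch by the Gershgorin disk radii and centers of that matrix -- a
    2N-dimensional spectral-inclusion feature vector that avoids an
    eigendecomposition.  Includes a seeded simulator for synthetic
    extracellular action potentials at configurable signal-to-noise ratios
    and a surrogate EEG generator, a 1-D convolutional network classifier
    harness with a support-vector-machine alternative, and a command-line
    interface for the simulate/extract/classify pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
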