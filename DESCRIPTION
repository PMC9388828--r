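Package: ezpte
Title: Epileptogenic-Zone Network Biomarkers from Interictal Discharges via
    Phase Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Directed brain-network analysis of interictal epileptiform
    discharges (IEDs) recorded with intracranial EEG (ECoG). Implements
    time-frequency phase-transfer-entropy mapping for analysis-window
    selection, construction of thresholded directed adjacency matrices,
    seven per-electrode graph metrics (betweenness centrality, clustering
    coefficient, local efficiency, in/out degree and strength) with
    power-spectrum compensation, and zone-level statistics (Mann-Whitney
    tests, logistic classification) contrasting epileptogenic, margin and
    normal zones. Includes a synthetic ECoG generator with ground-truth
    epileptogenic coupling, a minimal EDF reader/writer, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
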