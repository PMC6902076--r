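Package: dynconn
Title: Dynamic Functional Connectivity States and Brain Network Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional network connectivity analysis
    for ROI time series: confound regression (Friston-24, polynomial trends)
    and ideal band-pass conditioning, windowed Fisher-z connectivity tensors,
    dynamic connectivity-variability matrices with covariate-adjusted edgewise
    group tests, k-means decomposition of windowed connectivity into recurring
    states under correlation distance with cluster-validity k selection and
    temporal state metrics (dwell time, frequency, transitions), and
    sparsity-thresholded binary-graph global/local efficiency with AUC
    summaries. Includes a regime-switching multivariate Gaussian cohort
    simulator with known state covariances, Markov dwell structure,
    demographics and motion traces, so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
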