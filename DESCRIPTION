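Package: ricesits
Title: Phenology-Aware Paddy Rice Mapping from Satellite Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps paddy rice from Sentinel-2-like multispectral time series in
    cloud-prone, fragmented agricultural landscapes. Reconstructs cloud-gapped
    vegetation-index trajectories (quality masking, Savitzky-Golay smoothing on
    irregular day-of-year grids, harmonic-regression gap filling), derives a
    phenological feature set (NDVI, LSWI, EVI plus their temporal differences
    TDVI and normalized change rates NCRVI), and classifies per-pixel series
    with an enhanced time-series transformer with parallel three-branch feature
    embedding, channel attention, seasonal/day-of-year adaptive positional
    encoding, a phenology attention gate, and an optional 3D-convolutional
    spatio-spectral patch branch. Includes polygon-group-isolated train/test
    splitting, AdamW training with cosine annealing, confusion-matrix metrics
    with Cohen's kappa, McNemar paired classifier comparison, and a synthetic
    scene generator emulating rice phenology, cloud-induced missingness and
    polygon-correlated sampling so the full pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    graphics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    e1071
Config/testthat/edition: 3
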