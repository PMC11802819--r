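Package: eegseek
Title: Seed-Search Extremely Randomized Trees for Inner-Speech EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of four-class inner-speech EEG epochs with a
    seed-searched extremely randomized decision tree ("BruteExtraTree"):
    many independently seeded trees are trained and the development-set
    argmax is kept. Includes the surrounding benchmark stack: an HDF5
    epoch container, a multi-subject synthetic EEG generator with planted
    class structure, six feature-extraction pipelines (raw, ICA, PCA,
    pairwise and one-vs-all common spatial patterns, common average
    reference plus discrete wavelet features, and their concatenation),
    leakage-free subject-dependent and subject-independent splitting,
    and a reproducible model-by-preprocessing accuracy grid with CSV
    output and heatmap plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    signal,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
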