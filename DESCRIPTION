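Package: wptmix
Title: Wavelet Packet Super-Resolution and Automated Mixture Analysis for 1H NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts 1D 1H NMR spectra into super-resolved "shift" spectra by
    collapsing scalar-coupling multiplets with a Daubechies-9 wavelet packet
    approximation cascade, builds per-molecule shift-spectral libraries, and
    predicts the molecular composition of small-molecule mixtures with a
    four-step algorithm: wavelet conversion, library peak matching, and two
    gradient-descent optimisations over shift-peak and full wavelet-spectrum
    design matrices. Includes a synthetic multiplet simulator for generating
    libraries and augmented mixture datasets with ground truth, plus scoring
    and benchmarking utilities (true/false positive rates by mixture size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
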