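Package: phosnet
Title: Data-Driven Inference of Phosphoprotein Signaling Networks from
    Ligand-Screen Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs signed, directed phosphoprotein signaling networks
    from short fold-change time courses of ligand-stimulation screens.
    Protein levels at one early time point are regressed on levels at the
    previous time point with single-output partial least squares; coefficient
    significance is assessed against a permutation null built from
    output-shuffled models; models are accepted by K-fold cross-validation
    with F-tests and a variance-captured gate; significant coefficients are
    refit as minimal least-squares models and assembled into a signed digraph
    for path enumeration, edge-consistency classification of experiments,
    and numerical-integration extrapolation to later time points. Includes a
    synthetic ligand-screen generator driven by a known sparse signed linear
    dynamical system so the full pipeline can be exercised and benchmarked
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
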