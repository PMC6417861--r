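Package: parpolar
Title: Curvature-Dependent PAR Polarity Symmetry Breaking in the C. elegans Zygote
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mass-conserving one-dimensional reaction-diffusion-advection model
    of the antagonistic anterior and posterior PAR proteins of the C. elegans
    zygote, coupled to an active-gel description of cortical flow and to a
    curvature-dependent membrane attachment rate for the posterior species.
    Simulates symmetry breaking with and without a localized contractility
    trigger, in elliptical and triangular embryo geometries, sweeps phase
    diagrams over the attachment-gain and contractility-feedback parameters,
    and classifies steady states by their posterior-domain count. Also
    implements the accompanying quantification operators: domain-extent
    detection on fluorescence kymographs and multipass cross-correlation
    particle image velocimetry, exercised on synthetic fixtures with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
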