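Package: nirselect
Title: Wavelength Selection and Origin Discrimination for Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics toolkit for geographic-origin discrimination of
    medicinal fungal material from near-infrared (NIR) diffuse-reflectance
    spectra. Provides spectra containers and CSV I/O on a uniform wavenumber
    grid, spectral pretreatment (Norris gap-segment smoothing, Savitzky-Golay
    second derivative, autoscaling) and standard-deviation band selection,
    Hotelling T2 / Q-residual outlier screening, Kennard-Stone sample set
    partitioning, four Monte-Carlo and projection wavelength-selection
    algorithms (competitive adaptive reweighted sampling, Monte-Carlo
    uninformative variable elimination, subwindow permutation analysis, and
    latent-projective-graph vertex detection) fused by consensus voting,
    PLS-DA evaluation with the Galtier membership rule, and stepwise
    Wilks-lambda screening feeding Fisher linear discriminant functions with
    leave-one-out validation. A synthetic spectra generator with planted
    class-discriminating absorption bands makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
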