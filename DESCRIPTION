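Package: headfit
Title: Head Tissue Optical Properties from Multidistance CW-NIRS by Monte Carlo Curve Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies in-vivo absorption and transport scattering spectra of
    scalp, skull, and gray matter from multidistance continuous-wave
    near-infrared reflectance. Provides a voxel-based white Monte Carlo photon
    transport engine with per-compartment pathlength recording, a transport
    scattering lookup table with microscopic Beer-Lambert rescaling and spline
    interpolation, a numerical-aperture conversion regression, a feedforward
    neural-network surrogate forward model, multi-start constrained spectral
    curve fitting with chromophore-based parameterization, two-stage
    multiple-solution selection with tie-breaker detectors, and Monte Carlo
    based uncertainty quantification. Includes a synthetic layered head-model
    generator standing in for MRI segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
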