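Package: trnirs
Title: Uncertainty Propagation for Depth-Resolved Time-Resolved
    Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning multi-wavelength time-resolved near-infrared
    spectroscopy (TR-NIRS) measurements of hemodynamic and metabolic brain
    signals.  A layered Monte Carlo photon-transport kernel generates
    distributions of time of flight (DTOFs) and per-layer pathlength
    statistics for a three-layer head model (scalp, skull, brain).  Moments
    of the DTOF (total counts, mean time of flight, variance) are propagated
    under Poisson photon noise through the moments-method covariance model to
    standard deviations of recovered absorption changes per layer, and on
    through the Beer-Lambert law to standard deviations of chromophore
    concentration changes (oxy-/deoxyhemoglobin, oxidised
    cytochrome-c-oxidase).  Scanning utilities rank wavelength sets,
    including bands of 16 consecutive wavelengths and evenly spread sets, by
    the uncertainty of cytochrome-c-oxidase recovery in the brain, optionally
    weighting by a detector spectral responsivity curve.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
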