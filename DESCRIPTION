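Package: nm2motility
Title: Simulation and Analysis of Processive Nonmuscle Myosin 2 Filament Motility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the processive movement of nonmuscle myosin 2
    (NM2) bipolar filaments on actin in single-filament TIRF motility assays.
    Provides the closed-form ensemble duty-ratio model for motor ensembles, an
    exact event-driven (Gillespie) simulator of motor attachment/detachment and
    filament translocation including headless-tail co-filaments, paralog
    mixtures and a viscosity-dependent rescue window, a synthetic TIRF movie
    renderer with Poisson shot noise and Gaussian read noise, a
    Laplacian-of-Gaussian spot detector with optimal linear-assignment track
    linking and gap closing, and the downstream estimators: intensity-based
    filament stoichiometry, censored single-exponential run-length fits,
    Gaussian velocity fits, run-length versus motor-number regression with
    x-intercept, and kymograph construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
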