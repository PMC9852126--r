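Package: hemogam
Title: Additive-Model Decomposition of Hemodynamic Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes hemodynamic recordings from mechanically ventilated
    patients into additive smooth components: a cardiac-cycle effect, a
    respiratory-cycle effect, their interaction and a slow trend. Smooths are
    penalized cubic and cyclic cubic regression splines with curvature
    penalties, fitted by penalized least squares with REML selection of the
    smoothing parameters, an optional AR(1) residual model and an optional
    median (quantile) loss for artifact-contaminated signals. From the fitted
    respiratory smooth of a pulse-pressure series the package derives pulse
    pressure variation (PPV) with a simulation-based confidence interval.
    Includes beat detection, cycle-position annotation, respiratory-rate
    estimation, a synthetic waveform generator with known ground truth, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
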