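Package: mimoxkin
Title: Kinetic Modeling of Metalloporphyrin-Catalyzed Biomimetic Drug Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation models of
    FeTPPS-catalyzed biomimetic oxidation of drug substrates under one-shot
    and continuous oxidant dosing: catalyst activation by tert-butyl
    hydroperoxide, substrate oxidation by the activated iron-oxo species,
    and oxidative catalyst degradation, with an optional non-catalytic
    oxidation pathway. Provides nonlinear least-squares parameter estimation
    (multistart Levenberg-Marquardt in log-parameter space), refinement of
    the initial response, parametric Monte Carlo confidence bands, practical
    identifiability diagnostics (standardized residuals, parameter
    correlations, AIC and adjusted R-squared model selection), a synthetic
    kinetic-data generator with heteroscedastic noise for parameter-recovery
    studies, and intrinsic-clearance normalization (k2/CL) with
    steady-state validity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
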