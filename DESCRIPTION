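Package: amylokin
Title: Bivariate Logistic-Weibull Modelling of Chemical Inhibition of
    Amyloid Aggregation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models sigmoid amyloid aggregation kinetics (ThT fluorescence
    or absorbance versus time) under increasing concentrations of a chemical
    inhibitor.  The aggregation curve is a logistic reparameterized in terms
    of the maximum growth, the maximum aggregation rate and the lag phase;
    each kinetic parameter can be modulated by a Weibull dose-response
    function of inhibitor concentration, yielding a bivariate response
    surface in time and concentration.  Provides nonlinear least-squares
    fitting with confidence intervals, significance-based pruning of
    dose-response blocks, a goodness-of-fit battery (adjusted R-squared,
    Fisher F consistency test, Durbin-Watson statistic, bias and accuracy
    factors), the EC50-at-tau global potency index, a synthetic-data
    generator with scenario presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
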