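Package: flushcurve
Title: Repeated Gompertz Growth Curves for Multi-Flush Crop Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the yield dynamics of perennial crops that
    produce successive flowering flushes, such as greenhouse cut roses.
    Detects flush boundaries in pooled cumulative daily-harvest series by
    smoothing (penalized spline or LOESS), differencing and locating local
    minima of the 7-day rolling harvest rate; fits a transformed Gompertz
    nonlinear mixed-effects model per flush by stochastic approximation EM
    (SAEM), with treatment fixed effects on the asymptote and growth-rate
    parameters and block/bed random effects; benchmarks each fit against a
    penalized-spline additive mixed model; and reports per-flush treatment
    contrasts with Wald confidence intervals. Includes a synthetic-data
    generator for randomized block multi-flush experiments with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    minpack.lm,
    nlme,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
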