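Package: slabspline
Title: Spike-at-Zero and Slab-and-Spline Dose-Response Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Regression tools for modeling dose-response curves of
    semicontinuous exposures (a point mass at zero plus a continuous
    positive part) without forcing the curve or its confidence band
    through the origin. Provides spike-at-zero indicator terms, natural
    cubic spline bases anchored at zero, and a slab-and-spline basis that
    constrains the fitted curve to be constant below the lower boundary
    knot while joining the spline with a continuous first derivative.
    Includes ordinary least squares fitting with Huber-White and
    cluster-robust sandwich standard errors, delta-method pointwise
    confidence bands for the dose-response contrast relative to a
    reference dose, and a Monte-Carlo engine that evaluates bias,
    empirical versus model-based standard errors, and coverage for a
    catalog of nine modeling strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    sandwich,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
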