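Package: yieldclim
Title: Temperature-Drought Interactions in Crop Yield Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how year-to-year climate variability drives crop
    yield variability from gridded monthly temperature and drought (SPEI)
    data and regional production panels. Provides growing-season,
    crop-calendar and area-weighted climate aggregation; penalized-spline
    detrending of yields and climate; a hierarchical linear mixed model
    with per-region random slopes (diagonal covariance) and region-specific
    residual variance ratios fitted by profiled maximum likelihood;
    marginality-respecting backward elimination and single-region BIC
    selection; quantile-conditioned percent-yield-change effect curves with
    pointwise confidence intervals; leave-one-out cross-validation of
    nested model variants; and a measurement-error noise simulation.
    Includes a synthetic-data generator with known ground truth so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
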