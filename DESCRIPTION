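Package: ptcmap
Title: Vertex-Wise Population Tuning Curve Mapping of Spatial and
    Face-Part Selectivity
Version: 0.1.0
Authors@R:
    person("ptcmap", "developers", email = "ptcmap@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and fitting of one-dimensional Gaussian
    population tuning curves (pTCs) from BOLD time series, as used to map
    retinotopic elevation and face-part preferences on the cortical
    surface. Provides traveling-bar and traveling-window stimulus designs,
    discrete cosine transform band-pass preprocessing, a two-pass fitting
    procedure with pooled double-gamma HRF estimation, a fixed-peak
    mixture-of-Gaussians alternative with BIC model comparison, an
    empirical-null false-discovery-rate bound for R-squared thresholding,
    posterior-anterior gradient and cross-map correlation statistics with
    Fisher-z group tests, cumulative face-coverage curves with a
    label-shuffle permutation test, and a seeded synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
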