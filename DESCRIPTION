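Package: rehydkin
Title: Rehydration Kinetics and Quality Analysis of Pre-Cooked Dried Beans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the rehydration of pre-cooked dried legumes
    and for the associated quality analysis. Implements the Peleg, Weibull,
    exponential and first-order empirical uptake models and the series
    solution of Fick's second law with a freely estimated geometric factor;
    fits them per curve or jointly across rehydration temperatures through a
    single-step Arrhenius substitution that estimates the reference rate
    constant (or diffusivity) and the activation energy simultaneously.
    Includes derived quality indices (rehydration yield, relative rehydration
    moisture, CIELAB colour difference, degree of starch retrogradation) with
    ANOVA-based group comparison and compact letter displays, and untargeted
    volatile-fingerprint chemometrics: retention indices from an alkane
    ladder, internal-standard normalisation, NIPALS PLS-DA, variable
    identification (VID) coefficients and discriminant selection. A synthetic
    data generator reproduces the statistical structure of the measurements
    so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
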