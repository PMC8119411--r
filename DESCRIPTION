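Package: elbmr
Title: Estimated Lean Body Mass from Urinary Creatinine and Specific Gravity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of lean body mass from spot urine
    samples. Computes a monthly fruit availability index (FAI) from
    phenology censuses, filters overly dilute urine samples, calibrates
    creatinine against specific gravity by through-origin regression with
    linear and quadratic terms, and treats the residuals as estimated lean
    body mass (ELBM). ELBM is then modelled against fruit availability and
    age-sex class with generalized additive mixed models and linear mixed
    models. Includes a synthetic-data generator with explicit latent ground
    truth for parameter-recovery simulation, a CSV-based pipeline driver
    with a reproducibility manifest, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
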