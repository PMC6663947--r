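Package: grmbank
Title: Graded Response Model Calibration, Diagnostics, and Short-Form Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and refining patient-reported outcome scales
    with Samejima's graded response model. Implements marginal maximum
    likelihood (Bock-Aitkin EM) item calibration with observed-information
    standard errors, item fit (Orlando-Thissen S-X2), local dependence
    screening, limited-information model fit (M2, RMSEA) with AIC/BIC,
    two-group differential item functioning via Wald tests with iterative
    anchor purification, expected a-posteriori scoring, and deterministic
    content-constrained short-form construction. Ships a 51-item depression
    item-bank fixture with a DSM-5 content map, plus a synthetic-data module
    that generates graded responses under a standard-normal latent trait with
    controlled injections of DIF, local dependence, misfit, and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
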