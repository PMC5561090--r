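Package: ringwi
Title: Intrinsic Water-Use Efficiency from Tree-Ring Carbon Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes intrinsic water-use efficiency (Wi) and leaf gas-exchange
    diagnostics (discrimination, ci, ci/ca, ca - ci) from tree-ring carbon
    isotope ratios and an atmospheric CO2 / d13C record, applies a
    below-canopy source-air correction for soil-respired CO2, and estimates
    developmental trends (age, height, crown illumination) as well as
    backward-looking time trends in Wi. Includes a synthetic stand generator
    with known ground truth that demonstrates how developmental effects in
    size-structured forests can masquerade as CO2 or climate trends in
    classical tree-ring isotope chronologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
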