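Package: cvcbsi
Title: Fully-Automated Surveillance of Central Venous Catheter-Related
    Bloodstream Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based detection of central venous catheter-related
    bloodstream infection (CVC-BSI) from tabular electronic health record
    extracts. Implements two fully-automated surveillance algorithms
    (microbiology plus bedside symptoms, and microbiology only), episode
    enumeration with the 14-day repeat infection timeframe, healthcare-
    associated classification, diagnostic-accuracy statistics with Wilson
    score intervals and Cohen's kappa, stratified extrapolation with
    bootstrap percentile confidence intervals, incidence rate tables and
    time series, and a calibrated synthetic cohort generator for testing
    the whole pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
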