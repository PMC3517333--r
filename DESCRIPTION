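Package: paeeval
Title: Scoring and Criterion Validation of Web-Based Physical Activity
    Instruments Against Doubly Labeled Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring engines for two self-report physical activity
    instruments: a 24-hour activity record built on a 96-slot, 15-minute
    diary grid scored against a MET (metabolic equivalent) compendium, and
    a 7-day recall built on per-period intensity-class durations with a
    very-light fill of unaccounted time.  Both are converted to total and
    activity energy expenditure (TEE, AEE) and physical activity level
    (PAL).  The criterion side provides a full doubly-labeled-water (DLW)
    calculator (tracer dosing, log-linear elimination fits by the
    intercept method, dilution spaces, CO2 production and TEE via the
    abbreviated Weir equation) and basal metabolic rate from indirect
    calorimetry.  Method-comparison statistics (Pearson and partial
    correlation, Bland-Altman limits of agreement with trend test,
    compliance accounting, 3-SD outlier screening) and a synthetic
    crossover-cohort simulator with a ground-truth activity layer make the
    whole validation chain reproducible without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
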