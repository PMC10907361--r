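Package: thermophilr
Title: Thermophilisation of Ecological Communities from Occurrence Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify thermophilisation - the increasing prevalence of
    warm-affinity species in ecological communities under climate warming -
    from long-format community time-series, species occurrence records and
    gridded temperature climatologies. Estimates species temperature indices
    (STI) and thermal niche breadths from occurrences, applies inclusion
    filters and rarefaction-based sampling-effort standardisation, computes
    community temperature indices (CTI) and per-site thermophilisation rates,
    decomposes rates into species immigration and extirpation with exact
    one-sided sign tests, and fits linear mixed-effects driver models with
    nested random intercepts and Gaussian spatial correlation. Includes a
    virtual-species simulator with known ground truth for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
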