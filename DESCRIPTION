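Package: soilhmrisk
Title: Soil Heavy-Metal Pollution Indices, Probabilistic Health Risk and
    Source Apportionment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Risk-analysis chain for heavy metals in soil surveys: the
    geo-accumulation index and the Hakanson potential ecological risk index
    with grading thresholds re-scaled to the toxicity-coefficient total of
    the element panel; a Monte Carlo probabilistic human-health risk engine
    (ingestion, dermal contact and inhalation pathways; carcinogenic and
    non-carcinogenic endpoints for child and adult receptors); and
    uncertainty-weighted positive matrix factorization for source
    apportionment with robust-mode diagnostics. Includes a synthetic
    soil-survey generator with known latent source structure, non-detect
    handling (5/6 detection-limit substitution), CSV/YAML input and JSON
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
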