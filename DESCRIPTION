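Package: ptgrowth
Title: Coupled Light-Use Efficiency and Tree Carbon-Allocation Growth Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates annual tree-ring growth from monthly climate forcing by
    coupling a light-use-efficiency photosynthesis model with least-cost
    optimal ci/ca regulation to a geometric carbon-allocation tree growth
    model. Includes synthetic climate and CO2 forcing generators with
    glacial-style anomaly construction, driver preparation (vapour pressure
    deficit, photosynthetically active radiation, a Priestley-Taylor soil
    moisture index, elevation and paleo bias corrections, a two-year carbon
    accumulation window), approximate Bayesian computation calibration of
    allocation parameters against observed mean ring width, and the
    experiment suite used to analyse glacial versus modern juniper growth:
    modern validation, ci/ca elevation profiles and temperature/VPD swaps,
    CO2-gradient allocation optimization, climate-variable substitution
    sensitivity runs, and an accumulation-window regression diagnostic.
    Reads and writes Tucson/RWL ring-width files and plain tabular climate
    and CO2 series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
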