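Package: codstress
Title: Multi-Stressor Physiology Pipeline for Juvenile Atlantic Cod
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for a multi-stressor (freshening, warming,
    acidification) exposure experiment on juvenile Atlantic cod (Gadus
    morhua). Converts intermittent-flow respirometry oxygen traces into
    background-corrected mass-specific oxygen consumption and
    lowest-decile standard metabolic rate estimates; solves the seawater
    carbonate system (pCO2, DIC, calcite/aragonite saturation) from
    total-scale pH and total alkalinity; quantifies liver antioxidant
    assays (GST, GR, glutathione) from microplate kinetics; applies a
    median-gap rule for detecting bimodal within-treatment responses and
    Yates-corrected chi-square tests of ecotype association; and ships a
    seeded synthetic-data generator so the full pipeline is testable
    without the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
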