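Package: eavflat
Title: Translate Instrument EAV Exports into REDCap-Style Flat-Table Imports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Clinical-chemistry laboratory instruments export biomarker
    results as entity-attribute-value (EAV) CSV files, one measurement per
    row. Electronic data capture (EDC) systems such as REDCap import wide
    flat tables keyed by record id and event name. eavflat translates
    between the two: it reads the instrument EAV export, builds a five-level
    hierarchical intermediate (study, participant, event, biomarker, value),
    and fills the values into a flat-table template exported from the EDC,
    driven by a declarative mapping configuration that binds source columns
    to roles and maps instrument attribute names to EDC field names. It
    screens values against type and bounds rules before import, can push the
    filled table to a REDCap-compatible web API, and ships a synthetic
    longitudinal-study generator plus a command-line interface for use in
    study data pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    curl,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    callr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
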