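Package: trialcover
Title: Coverage Analysis of Clinical Trial Data Elements in CDA-Based Shared EHR Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing whether an HL7 CDA based shared electronic
    health record (EHR) system covers the data elements required for clinical
    trial feasibility checking, patient recruitment, and trial execution.
    Provides an in-memory model of a trial-concept repository and of CDA
    template building-block repositories, readers and writers for a documented
    DECOR-style XML dialect, an OMOP-style "Maps to" vocabulary crosswalk for
    cross-terminology code expansion, an exact code-based matcher that turns
    template code bindings into candidate concept-template mappings, a
    coverage analyzer producing per-use-case and per-group statistics with a
    YAML report, and a synthetic fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
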