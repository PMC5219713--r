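Package: odmconvert
Title: Bidirectional Conversion Between SPSS-Style Datasets and CDISC ODM 1.3.1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts spreadsheet-based research databases held as SPSS-style
    datasets (an ordered variable dictionary plus rectangular case data) into
    CDISC ODM 1.3.1 XML documents, and back. The forward direction maps the
    flat SPSS variable list into a default ODM study hierarchy (protocol,
    study event, form, item group), turns value labels into code lists,
    renders case data as ODM ClinicalData with per-subject keys, and reports
    every attribute the mapping drops or degrades. The reverse direction
    flattens an ODM metadata tree back into a variable dictionary with
    declared default display attributes. Includes an internal structural and
    referential-integrity validator for ODM documents, a portable plain-text
    dataset dialect (JSON dictionary + CSV cases) requiring no SPSS
    installation, synthetic fixture generators, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    stats,
    tools,
    utils,
    xml2
Suggests:
    foreign,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
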