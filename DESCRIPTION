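Package: faircombine
Title: FAIR Maturity Assessment of COMBINE Models and Archives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automatic FAIR (Findability, Accessibility,
    Interoperability, Reusability) maturity assessment for systems-biology
    models and COMBINE archives. Ships the COMBINE-adapted RDA FAIR
    indicator registry (84 indicators over four assessment targets: model,
    model metadata, archive, archive metadata), reads OMEX archives and
    SBML/CellML model files, proposes scores for automatically assessable
    indicators with evidence, merges manual scores, propagates logical
    dependencies between indicators to a fixed point, and aggregates and
    exports FAIRness summaries and radial-column chart data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    utils,
    stats,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
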