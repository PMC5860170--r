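Package: pathcanvas
Title: Interactive Pathway Diagram Rendering, Subpathway Highlighting and
    Editable Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with hierarchical pathway diagrams in the style
    of curated pathway knowledge bases. Renders SBGN-style lower-level pathway
    diagrams to SVG, computes coloured subpathway highlight boxes with label
    placement by maximal-empty-rectangle search, parses and manipulates
    interactive textbook-style higher-level pathway illustrations (annotated
    SVG with clickable regions), overlays hypergeometric over-representation
    analysis results (hit-fraction bars, p-value gradient colouring, FDR
    annotations, legend), and exports classic diagrams to editable OOXML
    presentations in which reaction lines are connectors attached by reference
    so they follow moved glyphs. Includes deterministic synthetic fixture
    generators for every input format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
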