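Package: rnatangle
Title: Topological Artifact Detection in Predicted 3D RNA Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits 3D RNA structure models for topological artifacts that
    arise in computational structure prediction. Detects backbone knots on
    the sugar-phosphate backbone via the Alexander polynomial under
    stochastic two-point chain closure with KMT chain reduction, and detects
    and classifies entanglements of secondary-structure elements (loops,
    dinucleotide steps, single strands) into lasso and interlace subclasses,
    including lasso-depth computation with a shallow/deep rule. Includes a
    batch pipeline producing per-model reports and cohort summaries
    stratified by target and method class, and a synthetic-structure
    generator that builds ground-truth knotted and entangled fixtures for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
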