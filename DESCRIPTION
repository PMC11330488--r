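Package: aggkin
Title: Kinetic Analysis of Amyloid Fibril and Oligomer Formation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemical-kinetics toolkit for amyloid aggregation assays at the
    bulk and single-molecule level. Provides forward models of fibril
    formation (primary nucleation, elongation, secondary nucleation of
    reaction order zero, fragmentation) as moment ODEs and a fast
    fixed-point analytical approximation; normalization and global
    multi-curve fitting of plate-reader kinetic traces with model
    comparison; the plateau-phase fibril-length model for estimating
    fragmentation rates and the fragmentation-only proliferation bound;
    oligomer population dynamics with model selection between primary- and
    fibril-catalysed origins; threshold-based oligomer quantification from
    confocal photon-count timetraces; and synthetic-data generators that
    emulate each assay for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
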