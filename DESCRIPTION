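Package: minicage
Title: Minimalistic Bead Models of Self-Assembled Cage Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained bead models of self-assembled cage
    molecules from parameterised ditopic, tritopic and tetratopic building
    blocks placed on named topology graphs, finds low-energy conformers
    under a harmonic bead-spring force field with excluded volume via a
    multi-step optimisation sequence, and maps which topologies are
    geometrically accessible across building-block angle space
    (self-sorting outcomes). Includes continuous shape measures of
    building-block centroid sets against ideal polyhedra and an
    approximate pore radius, XYZ/JSON structure input and output, and
    ggplot2 visualisations of stability surfaces and accessible topology
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
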