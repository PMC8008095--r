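Package: gangliosim
Title: Rule-Based Simulation of Ganglioside Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates the ganglioside biosynthetic reaction network by
    iterated application of glycosyltransferase rewrite rules to
    ceramide-linked glycan structure identifiers. Ten enzyme activities
    (glucosyl-, galactosyl-, N-acetylgalactosaminyl- and
    sialyltransferases) are represented as donor plus acceptor-pattern
    rules; expanding them to a fixed point yields the canonical network of
    41 ganglioside carbohydrates in 49 reactions. The package also assigns
    systematic Svennerholm and IUPAC ganglioside names, converts between
    structure identifiers, IUPAC condensed notation and Linear Code,
    simulates enzyme knockouts, infers the enzymes required to synthesise
    a target glycan, and exports networks as CSV, SBML Level 3, Graphviz
    DOT or edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
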