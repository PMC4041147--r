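Package: crnreduce
Title: Kron Reduction of Enzyme-Kinetic Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents kinetic biochemical reaction networks through their
    complex graph (complex stoichiometric matrix and state-dependent weighted
    Laplacian), simulates their dynamics, and reduces them by deleting
    complexes via Schur complementation of the Laplacian (complex balancing).
    Supports mass-action, reversible Michaelis-Menten, modifier and Hill rate
    laws written in a factored proportionality-constant/denominator form, an
    error-integral-ranked greedy procedure that automates the choice of
    deletions under a perturbation scenario, symbolic collapse of reversible
    Michaelis-Menten chains, and network input/output in a native JSON format
    and an SBML Level 3 subset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    xml2,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
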