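Package: alkaneGC
Title: Second-Order Group-Contribution Thermochemistry and
    Hydroisomerization Equilibria of Alkanes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts ideal-gas thermochemical properties of branched
    alkanes with a linear-regression group-contribution model whose
    descriptors are second-order groups (a central united atom together
    with the multiset of its bonded neighbors), fitted per temperature and
    condensed into quadratic temperature polynomials. Includes a
    united-atom molecular-graph toolkit with an acyclic SMILES parser and
    writer, shorthand alkane-name handling, constitutional-isomer
    enumeration and branch-pattern filters, gas- and adsorbed-phase
    hydroisomerization reaction-equilibrium distributions from Henry
    coefficients at infinite dilution, selectivity measures, and an
    automated generator of RASPA2 molecule and force-field definition
    files for Monte Carlo adsorption simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
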