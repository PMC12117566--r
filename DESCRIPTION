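Package: cgbuildr
Title: Coarse-Grained Membrane and Solvent System Builder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds simulation-ready coarse-grained membrane, solvent and
    protein systems from a single declarative specification. Lipid counts per
    leaflet are allocated as integers that minimize the deviation from the
    requested area per lipid and from the requested lipid ratios, lipids are
    placed as discs in the membrane plane and relaxed with a damped push-force
    scheme, solvent and ions are inserted on a rasterized grid from molarities
    with three charge-neutralization algorithms, and coordinates and topologies
    are written in GROMACS-compatible GRO and .top formats. Includes a fragment
    based lipid assembler, molecule import from structure plus topology files,
    and a synthetic fixture generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
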