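Package: embryosim
Title: Agent-Based Simulation of Early C. elegans Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of early Caenorhabditis elegans
    embryogenesis. Cell fate and division timing are driven by an invariant
    Sulston-style lineage tree; division orientation follows a three-component
    direction model (cell polarity, cell-cell squeeze, cell-eggshell squeeze)
    whose coefficients are fitted to observed division axes by minimizing
    summed angular error; positions follow a quasi-equilibrium spring-mass
    network relaxed by potential-energy minimization inside an ellipsoidal
    eggshell. A desk-scale tabular Q-learning module models directed
    single-cell migration through a crowded cell field with ordered sub-goals,
    emulating the anterior intercalation of the Cpaaa cell. A synthetic-data
    module generates lineages, observed-division datasets with known
    coefficients, and migration scenarios so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
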