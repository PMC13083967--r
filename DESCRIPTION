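Package: kmcreact
Title: Kinetic Monte Carlo Emulation of Biomolecular Reaction Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale biomolecular reaction emulator. Conformational
    ensembles of a molecular system are generated with a toy stochastic
    dynamics sampler, candidate reactions are assigned rates by pluggable
    physical, heuristic or table-driven surrogate models (Eyring barrier
    averaging for hydrogen atom transfer, a Bell force-dependent model for
    homolysis, a force/pH/surface-accessibility heuristic for hydrolysis,
    and a distance-and-angle heuristic for pyrimidine photodimerization),
    one reaction per cycle is selected by rejection-free kinetic Monte
    Carlo, and the selected reaction is effected by rewriting the molecular
    topology through elementary recipe steps. Includes analysis utilities
    for hydrogen-shift classification, selection probabilities, rate
    convergence, radical migration distances and quantum-yield summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
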