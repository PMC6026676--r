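Package: fluxscope
Title: Constraint-Based Analysis of Gut Bacterial Metabolic Networks
Version: 0.1.0
Authors@R: person("fluxscope", "developers", role = c("aut", "cre"),
    email = "maintainer@fluxscope.dev")
Description: Tools for constraint-based analysis of genome-scale metabolic
    models of gut bacteria: flux balance analysis with parsimonious
    tie-breaking, flux variability analysis, synthetic lethality of
    reactions and nutrient exchanges (single and double knockouts with an
    exhaustive oracle), pathway sensitivity to reaction blocking,
    minimal-sufficient-nutrient combination search under aerobic and
    anaerobic regimes, and growth-coupled extracellular production and
    consumption profiling with cross-organism interaction matrices.
    Includes a deterministic generator of toy metabolic models following
    AGORA conventions (cytosolic/extracellular compartments, EX_ exchange
    reactions with uptake as negative flux, a biomass objective, subsystem
    annotations) plus SBML Level 3 + fbc input/output, so every pipeline
    stage is testable without downloading reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Optional 'python' (>= 3.8) with scipy, used only by
    the alternative "scipy" linear-programming backend.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
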