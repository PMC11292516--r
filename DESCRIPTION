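Package: pangenus
Title: Pan-Genus Metabolic Models for Microbial Communities at Mixed
    Taxonomic Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds species-aware pan-genus metabolic models (PGMMs) by
    merging species-level genome-scale metabolic models that share a
    reaction namespace, formulates a composition-weighted panBiomass
    objective, and customizes the merged model to arbitrary species
    probability vectors. Assembles compartmentalized microbial community
    models from relative-abundance tables that mix species- and
    genus-level taxa (GSMM, PGMM, lumped-biomass and hybrid community
    types), applies diet constraints to exchange reactions, and evaluates
    metabolic potential with flux variability analysis: net exchange
    fluxes, Jaccard and normalized Euclidean distances, significant-flux
    fractions, flux-bandwidth landscapes over sampled compositions, and
    UPGMA similarity trees. Linear programs are solved with the GLPK
    command-line solver; models are read and written as SBML Level 3 with
    the FBC extension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GLPK (glpsol on the PATH)
Imports:
    Matrix,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
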