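Package: kimerge
Title: Horizontal Integration of Kinetic SBML Models
Version: 0.1.0
Authors@R:
    person("Model", "Integration Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic horizontal integration of kinetic ODE models
    encoded in SBML. Reads and validates SBML Level 2/3 models, extracts the
    semantic identity of model elements from MIRIAM RDF annotations, SBO terms
    and a structured naming scheme, computes the overlap of two models by
    annotation-based matching with manual post-editing, merges them into a
    single model under an explicit parameter-source policy, simulates the
    result under step-stimulus inputs, tests consistency with the original
    models' (synthetic) data via a chi-square-per-datapoint criterion, and
    restores consistency by goal-driven multi-experiment reparameterization
    of a minimal parameter subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
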