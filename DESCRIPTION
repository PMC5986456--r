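Package: permatyper
Title: Enterotyping, Permatyping and Paired Response Analysis for Gut
    Microbiome Interventions
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for paired gut-microbiome diet-intervention studies:
    abundance-table handling with taxonomic lineages and prevalence
    filtering, Jensen-Shannon / Bray-Curtis / generalized UniFrac
    dissimilarities, enterotyping (PAM with Calinski-Harabasz model
    selection) and its bootstrap stability refinement ("permatyping"),
    responder/non-responder discovery from paired dissimilarities with
    baseline-microbiota classification, PERMANOVA with paired permutation
    schemes plus simulation-based power and sample-size design,
    compositional (CLR) paired differential abundance, alpha-diversity and
    co-occurrence "cooperative" summaries, and a fully parameterized
    synthetic paired-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    cluster,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
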