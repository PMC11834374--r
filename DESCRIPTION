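Package: symnet
Title: Tripartite Aphid-Parasitoid-Symbiont Community Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how defensive endosymbiont strains are
    distributed across a host insect community sampled together with its
    natural enemies and food plants.  Builds focal-species by partner-taxon
    count matrices from long-format field observation tables, computes
    Bray-Curtis community similarity and gene-distance relatedness matrices,
    fits multiple matrix regression with randomization (MMRR) to test which
    ecological predictors explain symbiont strain sharing, measures bipartite
    network specialisation (H2') against Patefield fixed-marginal null models
    with standardised effect sizes, projects parasitoid-symbiont networks
    proportionally through shared hosts, screens diversity relationships with
    rarefaction, and ships a synthetic tripartite community generator with
    known ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
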