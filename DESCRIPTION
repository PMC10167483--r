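Package: mechassembly
Title: Assembly, Reliability Modeling and Application of Mechanistic Statement Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes mechanistic statements aggregated from multiple
    extraction sources (machine readers and curated databases), deduplicates
    them by canonical equivalence keys, organizes them into a refinement
    hierarchy over an entity ontology, and scores their reliability with
    parametric belief models (binomial, beta-binomial, and a two-parameter
    systematic/random-error model) fit by affine-invariant ensemble MCMC or
    maximum likelihood, as well as feature-based classifiers. Includes
    descriptive corpus statistics (mention-count power-law fitting,
    multi-reader overlap, empirical precision), reference protein-protein
    interaction comparison, gene codependency detection and explanation with
    network priors, and synthetic-data generators so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
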