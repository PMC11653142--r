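Package: flexrestrain
Title: pLDDT-Informed Distance Restraints for Coarse-Grained Protein
    Flexibility Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates residue-pair distance restraints for coarse-grained
    protein flexibility simulation from secondary structure and AlphaFold
    per-residue confidence (pLDDT) scores, including a four-category
    confidence-plus-structure scheme, evaluates a flat-bottom restraint
    potential with asymmetric penalty slopes, runs a stand-in CA-bead
    Monte Carlo sampler to exercise restraint sets end-to-end, and scores
    predicted per-residue fluctuation (RMSF) profiles against reference
    ensembles with a best-of-replicas Pearson correlation protocol.
    Includes synthetic structure and trajectory generators so the full
    pipeline is testable without external data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
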