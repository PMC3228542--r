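Package: ppidrug
Title: Druggability Assessment of Protein-Protein Interactions by Ensemble
    Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rates protein-protein interactions (PPIs) as potential
    small-molecule drug targets by an ensemble support-vector-machine
    procedure: a fixed positive set of known drug-target PPIs is repeatedly
    trained against negatives sampled at random from the unlabeled pool, and
    each candidate's druggability score is the fraction of the ensemble that
    votes it positive. Includes derivation of the structural, drug/chemical
    and functional attributes that feed the classifier (OMIM disease
    co-annotation, network degree, pathway/drug/paralog counts, GO-term and
    expression-profile similarity, PDB chain mapping with interface-contact
    checks, per-pocket scoring with max-aggregation), criteria-based search
    over scored interactions, annotated network export, and a synthetic-data
    generator for end-to-end calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
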