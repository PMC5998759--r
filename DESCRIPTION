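Package: rwrDTI
Title: Drug-Target Interaction Prediction with Random-Walk-with-Restart
    Weighted Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-target interactions by smoothing drug
    fingerprints and protein sequence descriptors over drug-drug and
    protein-protein interaction networks with a random walk with restart
    (RWR), then classifying concatenated pair vectors with a
    k-nearest-neighbour model under the cubic (Minkowski p = 3) distance.
    Includes readers for edge-list, pair-list, fingerprint and FASTA
    inputs, a 1287-dimensional protein primary-structure descriptor
    (amino acid and dipeptide composition, normalized Moreau-Broto,
    Moran and Geary autocorrelations, and composition, transition and
    distribution statistics), a guilt-by-association baseline weighting,
    balanced negative sampling with replicate sets, ROC and AUC
    evaluation with cross-validation and restart-probability sweeps, and
    a stochastic-block-model synthetic data generator for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'descriptors.R'
    'dti-model.R'
    'evaluation.R'
    'net-io.R'
    'propagation.R'
    'pipeline.R'
    'rwrDTI-package.R'
    'synthetic.R'
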