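#' InteractionNetwork: a weighted undirected interaction graph
#'
#' Holds a protein-protein (PPI) or drug-drug (DDI) interaction network as an
#' ordered node vector plus an undirected weighted edge table. Edge weights
#' are interaction confidence scores for PPIs and 1 for shared-target DDIs.
#' Isolated nodes are allowed (and kept) so that every entity with a feature
#' row also has a random-walk row.
#'
#' @slot nodeIds character vector of entity identifiers (unique, ordered).
#' @slot edgeTable data.frame with columns `from`, `to`, `weight`; each row an
#'   undirected edge stored with `from < to`; no self loops, no duplicates,
#'   weights strictly positive.
#'
#' @seealso [readPPI()], [buildDDISharedTarget()], [normalizeAdjacency()]
#' @export
setClass("InteractionNetwork",
    representation(nodeIds = "character", edgeTable = "data.frame"),
    prototype(nodeIds = character(0),
              edgeTable = data.frame(from = character(0), to = character(0),
                                     weight = numeric(0))))

setValidity("InteractionNetwork", function(object) {
    msg <- character(0)
    et <- object@edgeTable
    if (!all(c("from", "to", "weight") %in% names(et)))
        return("edgeTable must have columns from, to, weight")
    if (anyDuplicated(object@nodeIds))
        msg <- c(msg, "nodeIds must be unique")
    if (nrow(et)) {
        if (any(et$from == et$to))
            msg <- c(msg, "self-loops are not allowed")
        if (any(et$from > et$to))
            msg <- c(msg, "edges must be stored with from < to")
        if (anyDuplicated(paste(et$from, et$to, sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
        if (!all(c(et$from, et$to) %in% object@nodeIds))
            msg <- c(msg, "every edge endpoint must be in nodeIds")
        if (any(!is.finite(et$weight)) || any(et$weight <= 0))
            msg <- c(msg, "edge weights must be finite and > 0")
    }
    if (length(msg)) msg else TRUE
})

#' BipartiteDTI: known drug-target interaction pairs
#'
#' The positive class of the prediction task: a unique set of
#' (drug, protein) pairs. The drug and protein universes are the entities
#' induced by the pairs.
#'
#' @slot pairTable data.frame with character columns `drug`, `protein`;
#'   rows unique.
#' @seealso [readDTI()], [buildDDISharedTarget()], [makePairVectors()]
#' @export
setClass("BipartiteDTI",
    representation(pairTable = "data.frame"),
    prototype(pairTable = data.frame(drug = character(0),
                                     protein = character(0))))

setValidity("BipartiteDTI", function(object) {
    pt <- object@pairTable
    if (!all(c("drug", "protein") %in% names(pt)))
        return("pairTable must have columns drug, protein")
    if (anyDuplicated(paste(pt$drug, pt$protein, sep = "\r")))
        return("pairs must be unique")
    TRUE
})

#' FeatureMatrix: entities x features with an aligned identifier index
#'
#' A dense real matrix whose rows are entities (drugs or proteins) and whose
#' columns are named features -- raw fingerprints, protein descriptors, or
#' their network-weighted versions.
#'
#' @slot values numeric matrix; rownames are entity ids (unique), colnames
#'   are feature names.
#' @seealso [readFingerprints()], [proteinDescriptorMatrix()],
#'   [weightFeatures()]
#' @export
setClass("FeatureMatrix",
    representation(values = "matrix"),
    prototype(values = matrix(numeric(0), 0, 0)))

setValidity("FeatureMatrix", function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v))
        return("values must be a numeric matrix")
    if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
        msg <- c(msg, "rownames(values) must be unique entity ids")
    if (any(!is.finite(v)))
        msg <- c(msg, "feature values must be finite")
    if (length(msg)) msg else TRUE
})

#' AffinityMatrix: stacked random-walk-with-restart distributions
#'
#' Row i is the converged restart-walk distribution started from seed node i,
#' so entry (i, j) measures how closely node j is connected to seed i in the
#' network. Every row sums to 1 (mass conservation of the walk) and the
#' diagonal is at least the restart probability.
#'
#' @slot values square numeric matrix, identical row/col names (entity ids).
#' @slot restartC restart probability in (0, 1].
#' @seealso [affinityMatrix()], [weightFeatures()]
#' @export
setClass("AffinityMatrix",
    representation(values = "matrix", restartC = "numeric"))

setValidity("AffinityMatrix", function(object) {
    v <- object@values
    msg <- character(0)
    if (nrow(v) != ncol(v))
        return("affinity matrix must be square")
    if (!identical(rownames(v), colnames(v)))
        msg <- c(msg, "row and column names must match")
    if (length(object@restartC) != 1 ||
        object@restartC <= 0 || object@restartC > 1)
        msg <- c(msg, "restartC must be a single value in (0, 1]")
    if (nrow(v)) {
        if (min(v) < -1e-12)
            msg <- c(msg, "affinity entries must be non-negative")
        if (max(abs(rowSums(v) - 1)) > 1e-6)
            msg <- c(msg, "every affinity row must sum to 1 (tol 1e-6)")
        if (min(diag(v)) < object@restartC - 1e-9)
            msg <- c(msg, "diagonal entries must be >= restartC")
    }
    if (length(msg)) msg else TRUE
})

#' RWRConfig: random-walk-with-restart settings
#'
#' @slot restartC restart probability c in (0, 1]; default 0.25, the value
#'   that optimises independent-test performance for this method.
#' @slot tol L1 convergence tolerance of the power iteration.
#' @slot maxIter iteration cap; exceeding it is an error.
#' @seealso [rwr()], [affinityMatrix()]
#' @export
setClass("RWRConfig",
    representation(restartC = "numeric", tol = "numeric", maxIter = "numeric"),
    prototype(restartC = 0.25, tol = 1e-10, maxIter = 1000L))

setValidity("RWRConfig", function(object) {
    msg <- character(0)
    if (object@restartC <= 0 || object@restartC > 1)
        msg <- c(msg, "restartC must lie in (0, 1]")
    if (object@tol <= 0)
        msg <- c(msg, "tol must be > 0")
    if (object@maxIter < 1)
        msg <- c(msg, "maxIter must be >= 1")
    if (length(msg)) msg else TRUE
})

#' PairDataset: labelled drug-target pair vectors
#'
#' Feature rows for labelled (drug, protein) pairs: each row is the drug
#' feature block followed by the protein feature block. Negatives carry the
#' index of the replicate negative set they belong to; positives carry 0.
#'
#' @slot pairIds data.frame with columns `drug`, `protein`.
#' @slot X numeric matrix of pair vectors, one row per pair.
#' @slot y integer labels (1 positive, 0 negative).
#' @slot negativeSet integer replicate index per row (0 for positives).
#' @slot drugWidth number of leading columns holding the drug block.
#' @seealso [makePairVectors()], [buildPairDataset()], [knnFit()]
#' @export
setClass("PairDataset",
    representation(pairIds = "data.frame", X = "matrix", y = "integer",
                   negativeSet = "integer", drugWidth = "integer"))

setValidity("PairDataset", function(object) {
    msg <- character(0)
    n <- nrow(object@X)
    if (nrow(object@pairIds) != n || length(object@y) != n ||
        length(object@negativeSet) != n)
        msg <- c(msg, "pairIds, X, y and negativeSet must align row-wise")
    if (!all(object@y %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0/1")
    if (any(object@y == 1L & object@negativeSet != 0L))
        msg <- c(msg, "positives must have negativeSet == 0")
    if (length(object@drugWidth) != 1 || object@drugWidth < 0 ||
        object@drugWidth > ncol(object@X))
        msg <- c(msg, "drugWidth must be in [0, ncol(X)]")
    if (length(msg)) msg else TRUE
})

#' KNNModel: k-nearest-neighbour classifier with cubic distance
#'
#' Stores the training matrix and labels for exact brute-force
#' nearest-neighbour scoring under the Minkowski distance with exponent 3
#' ("cubic kNN"). The cubic exponent accentuates large per-feature
#' differences, which is what makes network-weighted features effective.
#'
#' @slot X training matrix (standardized if `center`/`scale` are non-empty).
#' @slot y integer training labels (0/1).
#' @slot k number of neighbours.
#' @slot exponent Minkowski exponent; fixed at 3.
#' @slot center,scale per-feature training mean and standard deviation used
#'   to standardize queries; empty when standardization is off.
#' @seealso [knnFit()], [knnScore()], [cubicDistance()]
#' @export
setClass("KNNModel",
    representation(X = "matrix", y = "integer", k = "integer",
                   exponent = "numeric", center = "numeric",
                   scale = "numeric"),
    prototype(exponent = 3, center = numeric(0), scale = numeric(0)))

setValidity("KNNModel", function(object) {
    msg <- character(0)
    if (length(object@y) != nrow(object@X))
        msg <- c(msg, "y must align with rows of X")
    if (object@k < 1 || object@k > nrow(object@X))
        msg <- c(msg, "k must satisfy 1 <= k <= nrow(X)")
    if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a generated benchmark instance
#'
#' A self-consistent synthetic input set with the statistical structure the
#' method exploits: a modular (stochastic-block-model) PPI network, drugs
#' whose targets live inside one module (so co-module drugs share targets and
#' form DDI cliques), module-templated fingerprints, and random protein
#' sequences. `ddi` is always exactly `buildDDISharedTarget(dti)`.
#'
#' @slot ppi,ddi [InteractionNetwork] objects.
#' @slot dti training positives as a [BipartiteDTI].
#' @slot testDti held-out positives (same module rule, disjoint from `dti`).
#' @slot sequences `Biostrings::AAStringSet` of protein sequences.
#' @slot fingerprints drug fingerprint [FeatureMatrix] (binary).
#' @slot moduleOf named integer: module assignment of every protein and drug.
#' @slot params list of generator parameters, including `rngSeed`.
#' @seealso [generateWorld()], [writeWorld()]
#' @export
setClass("SyntheticWorld",
    representation(ppi = "InteractionNetwork", ddi = "InteractionNetwork",
                   dti = "BipartiteDTI", testDti = "BipartiteDTI",
                   sequences = "ANY", fingerprints = "FeatureMatrix",
                   moduleOf = "integer", params = "list"))
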