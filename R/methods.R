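#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an InteractionNetwork
#'
#' Builds a validated undirected weighted network from an edge table,
#' canonicalising edge orientation (`from < to`), dropping self-loops and
#' resolving duplicate edges by keeping the maximum weight.
#'
#' @param from,to character vectors of edge endpoints.
#' @param weight numeric edge weights (> 0); recycled if length 1.
#' @param nodes optional character vector of node ids; endpoints are added
#'   to it, so pass it to keep isolated nodes.
#' @return An [InteractionNetwork-class] object.
#' @examples
#' net <- interactionNetwork(c("a", "b"), c("b", "c"), weight = 1)
#' nodeIds(net)
#' @export
interactionNetwork <- function(from, to, weight = 1, nodes = character(0)) {
    stopifnot(length(from) == length(to))
    weight <- rep_len(as.numeric(weight), length(from))
    keep <- from != to
    from <- as.character(from)[keep]
    to <- as.character(to)[keep]
    weight <- weight[keep]
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    key <- paste(from, to, sep = "\r")
    if (anyDuplicated(key)) {
        w <- tapply(weight, key, max)
        first <- !duplicated(key)
        ord <- match(key[first], names(w))
        from <- from[first]; to <- to[first]; weight <- as.numeric(w[ord])
    }
    nodes <- unique(c(as.character(nodes), from, to))
    new("InteractionNetwork", nodeIds = nodes,
        edgeTable = data.frame(from = from, to = to, weight = weight,
                               stringsAsFactors = FALSE))
}

#' Construct a BipartiteDTI
#'
#' @param drug,protein character vectors of equal length; duplicate pairs are
#'   collapsed.
#' @return A [BipartiteDTI-class] object.
#' @examples
#' dti <- bipartiteDTI(c("d1", "d1"), c("p1", "p2"))
#' pairs(dti)
#' @export
bipartiteDTI <- function(drug, protein) {
    stopifnot(length(drug) == length(protein))
    pt <- unique(data.frame(drug = as.character(drug),
                            protein = as.character(protein),
                            stringsAsFactors = FALSE))
    rownames(pt) <- NULL
    new("BipartiteDTI", pairTable = pt)
}

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix with entity ids as rownames.
#' @param entityIds optional rownames override.
#' @return A [FeatureMatrix-class] object.
#' @export
featureMatrix <- function(values, entityIds = NULL) {
    values <- as.matrix(values)
    if (!is.null(entityIds)) rownames(values) <- entityIds
    new("FeatureMatrix", values = values)
}

#' Construct an RWRConfig
#'
#' @param restartC restart probability in (0, 1]; default 0.25.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param maxIter maximum iterations; default 1000.
#' @return An [RWRConfig-class] object.
#' @export
rwrConfig <- function(restartC = 0.25, tol = 1e-10, maxIter = 1000L) {
    new("RWRConfig", restartC = restartC, tol = tol, maxIter = maxIter)
}

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nodeIds", "InteractionNetwork", function(x, ...) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("edges", "InteractionNetwork", function(x, ...) x@edgeTable)

#' @rdname accessors
#' @export
setMethod("pairs", "BipartiteDTI", function(x, ...) x@pairTable)

#' @rdname accessors
#' @export
setMethod("drugIds", "BipartiteDTI",
          function(x, ...) sort(unique(x@pairTable$drug)))

#' @rdname accessors
#' @export
setMethod("proteinIds", "BipartiteDTI",
          function(x, ...) sort(unique(x@pairTable$protein)))

#' @rdname accessors
#' @export
setMethod("entityIds", "FeatureMatrix", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x, ...) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("entityIds", "AffinityMatrix", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("featureValues", "AffinityMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("restartC", "AffinityMatrix", function(x, ...) x@restartC)

#' @rdname accessors
#' @export
setMethod("restartC", "RWRConfig", function(x, ...) x@restartC)

## ---- show -----------------------------------------------------------------

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d nodes, %d undirected edges\n",
                length(object@nodeIds), nrow(object@edgeTable)))
    if (nrow(object@edgeTable))
        cat(sprintf("  weight range: [%g, %g]\n",
                    min(object@edgeTable$weight),
                    max(object@edgeTable$weight)))
})

setMethod("show", "BipartiteDTI", function(object) {
    cat(sprintf("BipartiteDTI: %d pairs, %d drugs, %d proteins\n",
                nrow(object@pairTable), length(drugIds(object)),
                length(proteinIds(object))))
})

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix: %d entities x %d features\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "AffinityMatrix", function(object) {
    cat(sprintf("AffinityMatrix: %d x %d, restart probability c = %g\n",
                nrow(object@values), ncol(object@values), object@restartC))
})

setMethod("show", "PairDataset", function(object) {
    cat(sprintf(
        "PairDataset: %d pairs x %d features (%d+, %d-; %d negative sets)\n",
        nrow(object@X), ncol(object@X), sum(object@y == 1L),
        sum(object@y == 0L), max(c(0L, object@negativeSet))))
})

setMethod("show", "KNNModel", function(object) {
    cat(sprintf("KNNModel: %d training rows, k = %d, Minkowski exponent %g\n",
                nrow(object@X), object@k, object@exponent))
})

setMethod("show", "SyntheticWorld", function(object) {
    cat("SyntheticWorld\n")
    cat(sprintf("  PPI: %d proteins, %d edges\n", length(nodeIds(object@ppi)),
                nrow(edges(object@ppi))))
    cat(sprintf("  DDI: %d drugs, %d edges\n", length(nodeIds(object@ddi)),
                nrow(edges(object@ddi))))
    cat(sprintf("  DTI: %d training pairs, %d held-out pairs\n",
                nrow(pairs(object@dti)), nrow(pairs(object@testDti))))
})
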