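#' @include methods.R
NULL

#' Normalized adjacency matrix of an interaction network
#'
#' Builds the (sparse) weighted adjacency matrix and normalizes it for the
#' restart walk. The default is column-stochastic normalization
#' \eqn{\tilde A_{ij} = w_{ij} / \sum_k w_{kj}} -- each column distributes a
#' unit of outgoing mass over the node's neighbours in proportion to edge
#' weight; columns of isolated nodes are all zero. A symmetric
#' (\eqn{D^{-1/2} A D^{-1/2}}) variant is available.
#'
#' @param net An [InteractionNetwork-class].
#' @param mode "column" (stochastic, default) or "symmetric".
#' @return A sparse `Matrix` with node ids as dimnames.
#' @examples
#' net <- interactionNetwork("A", "B")
#' as.matrix(normalizeAdjacency(net))
#' @export
normalizeAdjacency <- function(net, mode = c("column", "symmetric")) {
    mode <- match.arg(mode)
    ids <- nodeIds(net)
    n <- length(ids)
    et <- edges(net)
    i <- match(et$from, ids); j <- match(et$to, ids)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(et$weight, 2), dims = c(n, n),
                              dimnames = list(ids, ids))
    deg <- Matrix::colSums(A)
    inv <- ifelse(deg > 0, 1 / deg, 0)
    out <- if (mode == "column") {
        A %*% Matrix::Diagonal(n, inv)
    } else {
        s <- Matrix::Diagonal(n, sqrt(inv))
        s %*% A %*% s
    }
    dimnames(out) <- list(ids, ids)
    out
}

## Column-stochastic transition matrix with dangling (zero-out-degree)
## columns made self-absorbing, so walk mass is conserved for every seed and
## an isolated seed converges to a point mass at itself.
.transitionMatrix <- function(net) {
    At <- normalizeAdjacency(net, mode = "column")
    deg <- Matrix::colSums(At)
    dangling <- which(deg == 0)
    if (length(dangling))
        At <- At + Matrix::sparseMatrix(i = dangling, j = dangling,
                                        x = 1, dims = dim(At),
                                        dimnames = dimnames(At))
    At
}

.rwrIterate <- function(At, Q, cRestart, tol, maxIter) {
    R <- Q
    for (iter in seq_len(maxIter)) {
        Rnew <- (1 - cRestart) * (At %*% R) + cRestart * Q
        deltaL1 <- max(Matrix::colSums(abs(Rnew - R)))
        R <- Rnew
        if (deltaL1 < tol) return(R)
    }
    stop(sprintf("random walk did not converge in %d iterations (L1 residual %.3g)",
                 maxIter, deltaL1))
}

#' Random walk with restart from a single seed
#'
#' Iterates \eqn{r \leftarrow (1-c)\tilde A r + c q} from \eqn{r = q} (the
#' indicator of the seed) until the L1 change drops below `tol`. The fixed
#' point is the seed's affinity distribution: non-negative, summing to 1
#' over the seed's connected component, zero outside it, with the seed's own
#' entry at least `c` (the walker restarts there with probability `c` at
#' every step).
#'
#' @param net An [InteractionNetwork-class].
#' @param seedId node id of the seed; must be in the network.
#' @param config An [RWRConfig-class]; default c = 0.25, tol = 1e-10.
#' @return named numeric affinity vector over `nodeIds(net)`.
#' @examples
#' net <- interactionNetwork("A", "B")
#' rwr(net, "A", rwrConfig(restartC = 0.5))   # (2/3, 1/3)
#' @export
rwr <- function(net, seedId, config = rwrConfig()) {
    validObject(config)
    ids <- nodeIds(net)
    if (!seedId %in% ids)
        stop("seed '", seedId, "' is not a node of the network")
    At <- .transitionMatrix(net)
    q <- numeric(length(ids)); names(q) <- ids
    q[seedId] <- 1
    r <- .rwrIterate(At, q, config@restartC, config@tol, config@maxIter)
    r <- as.numeric(r); names(r) <- ids
    r
}

#' Affinity matrix: restart-walk distributions for every seed
#'
#' Runs the restart walk from every node (all seeds propagated jointly) and
#' stacks the converged distributions as rows: `W[i, j]` is how closely node
#' j is connected to seed node i. Every row sums to 1 and the diagonal is at
#' least the restart probability.
#'
#' @param net An [InteractionNetwork-class].
#' @param config An [RWRConfig-class].
#' @return An [AffinityMatrix-class].
#' @export
affinityMatrix <- function(net, config = rwrConfig()) {
    validObject(config)
    ids <- nodeIds(net)
    n <- length(ids)
    At <- .transitionMatrix(net)
    Q <- Matrix::Diagonal(n)
    R <- .rwrIterate(At, Q, config@restartC, config@tol, config@maxIter)
    W <- t(as.matrix(R))           # column per seed -> row per seed
    dimnames(W) <- list(ids, ids)
    W[W < 0] <- 0
    new("AffinityMatrix", values = W, restartC = config@restartC)
}

#' Closed-form restart-walk affinity
#'
#' Direct solve of the fixed point, \eqn{r = c (I - (1-c)\tilde A)^{-1} q},
#' using the same transition matrix as the iterative walk. Provided as an
#' exact reference for small networks; the iterative form is the default
#' because it scales to large sparse interactomes.
#'
#' @inheritParams rwr
#' @return named numeric affinity vector.
#' @export
rwrClosedForm <- function(net, seedId, config = rwrConfig()) {
    ids <- nodeIds(net)
    if (!seedId %in% ids)
        stop("seed '", seedId, "' is not a node of the network")
    At <- as.matrix(.transitionMatrix(net))
    n <- length(ids)
    q <- numeric(n); q[match(seedId, ids)] <- 1
    r <- config@restartC * solve(diag(n) - (1 - config@restartC) * At, q)
    r <- as.numeric(r); names(r) <- ids
    r
}

#' Weight a feature matrix by network affinity
#'
#' The core feature-smoothing step: each entity's weighted feature vector is
#' the affinity-weighted mixture of all entities' raw features,
#' `weighted[i, ] = sum_j W[i, j] * F[j, ]`, i.e. the matrix product `W F`
#' aligned on entity ids. Because each affinity row is a probability
#' distribution, every weighted value is a convex combination over the
#' seed's connected component, and the seed retains at least a `c` fraction
#' of its own features.
#'
#' @param W An [AffinityMatrix-class].
#' @param F A [FeatureMatrix-class] covering at least the entities of `W`.
#' @return A [FeatureMatrix-class] in the entity order of `W`.
#' @export
weightFeatures <- function(W, F) {
    ids <- entityIds(W)
    missing <- setdiff(ids, entityIds(F))
    if (length(missing))
        stop("entities in affinity matrix missing from feature matrix: ",
             paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
    out <- featureValues(W) %*% featureValues(F)[ids, , drop = FALSE]
    rownames(out) <- ids
    featureMatrix(out)
}

#' Mean pairwise Euclidean feature distance
#'
#' Average Euclidean distance over all unordered pairs of the selected
#' feature rows. Used to quantify the contraction that network weighting
#' induces among entities that are adjacent in the network (e.g. the drugs
#' of a shared-target clique): after restart-walk weighting their features
#' mix, so the mean within-clique distance drops relative to the raw
#' features.
#'
#' @param F A [FeatureMatrix-class].
#' @param ids entity ids to compare (>= 2); default all.
#' @return mean pairwise distance (scalar).
#' @export
meanPairwiseDistance <- function(F, ids = entityIds(F)) {
    if (length(ids) < 2)
        stop("need at least two entities to compare")
    v <- featureValues(F)[ids, , drop = FALSE]
    mean(stats::dist(v))
}

#' Guilt-by-association baseline weighting
#'
#' One-hop feature averaging: node i's weighted features are the
#' edge-weight-proportional mixture of its direct neighbours' features plus
#' its own features with weight `includeSelfWeight`, the mixture normalized
#' to sum 1. Unlike the restart walk this sees only direct neighbours, and a
#' strongly connected node's own signal can be swamped -- the limitation the
#' restart walk addresses.
#'
#' @param net An [InteractionNetwork-class].
#' @param F A [FeatureMatrix-class] covering the network's nodes.
#' @param includeSelfWeight weight given to the node's own features before
#'   normalization (default 1, on the scale of edge weights).
#' @return A [FeatureMatrix-class] in network node order. Isolated nodes
#'   keep their original features.
#' @export
gbaWeighting <- function(net, F, includeSelfWeight = 1) {
    ids <- nodeIds(net)
    missing <- setdiff(ids, entityIds(F))
    if (length(missing))
        stop("network nodes missing from feature matrix: ",
             paste(utils::head(missing, 10), collapse = ", "))
    n <- length(ids)
    et <- edges(net)
    i <- match(et$from, ids); j <- match(et$to, ids)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(et$weight, 2), dims = c(n, n))
    M <- A + Matrix::Diagonal(n, includeSelfWeight)
    rs <- Matrix::rowSums(M)
    zero <- rs == 0                # isolated node with zero self-weight
    M <- Matrix::Diagonal(n, ifelse(zero, 0, 1 / rs)) %*% M
    if (any(zero))                 # such nodes keep their own features
        M <- M + Matrix::sparseMatrix(i = which(zero), j = which(zero),
                                      x = 1, dims = c(n, n))
    out <- as.matrix(M %*% featureValues(F)[ids, , drop = FALSE])
    rownames(out) <- ids
    featureMatrix(out)
}
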