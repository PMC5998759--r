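#' @include methods.R
NULL

#' Assemble drug-target pair feature vectors
#'
#' Each (drug, protein) pair is represented by the drug feature block
#' followed by the protein feature block; with 1024 fingerprint bits and the
#' 1287-dimensional protein descriptor this gives the 2311-dimensional pair
#' vector the classifier consumes.
#'
#' @param pairsDf data.frame with columns `drug`, `protein` (e.g.
#'   `pairs(dti)`).
#' @param drugF,protF [FeatureMatrix-class] objects (raw or weighted).
#' @param strict error if a pair's drug or protein has no feature row
#'   (default); otherwise drop such pairs with a warning.
#' @return list with `X` (matrix, one row per kept pair) and `pairIds`
#'   (data.frame).
#' @export
makePairVectors <- function(pairsDf, drugF, protF, strict = TRUE) {
    di <- match(pairsDf$drug, entityIds(drugF))
    pj <- match(pairsDf$protein, entityIds(protF))
    bad <- is.na(di) | is.na(pj)
    if (any(bad)) {
        what <- paste(pairsDf$drug[bad], pairsDf$protein[bad], sep = "/")
        if (strict)
            stop("pairs with missing feature rows: ",
                 paste(utils::head(what, 10), collapse = ", "),
                 if (sum(bad) > 10) sprintf(" (+%d more)", sum(bad) - 10))
        warning(sprintf("dropping %d pair(s) with missing feature rows",
                        sum(bad)))
        pairsDf <- pairsDf[!bad, , drop = FALSE]
        di <- di[!bad]; pj <- pj[!bad]
    }
    X <- cbind(featureValues(drugF)[di, , drop = FALSE],
               featureValues(protF)[pj, , drop = FALSE])
    rownames(X) <- NULL
    list(X = X, pairIds = data.frame(drug = pairsDf$drug,
                                     protein = pairsDf$protein,
                                     stringsAsFactors = FALSE))
}

#' Sample replicate sets of negative drug-target pairs
#'
#' Draws `nSets` independent negative sets, each with as many pairs as there
#' are positives, uniformly without replacement from the (drug, protein)
#' combinations over the observed drug and protein sets that are not known
#' positives. Replicate sets are drawn independently and may overlap each
#' other, never the positives.
#'
#' @param dti A [BipartiteDTI-class] of positives.
#' @param nSets number of replicate negative sets (default 20).
#' @param rngSeed integer seed; the draw is reproducible from it.
#' @param drugs,proteins optional entity universes; default the entities
#'   induced by `dti`.
#' @param nPerSet pairs per negative set; default the number of positives
#'   (balanced sampling).
#' @return list of `nSets` data.frames with columns `drug`, `protein`.
#' @export
sampleNegatives <- function(dti, nSets = 20, rngSeed = 1,
                            drugs = drugIds(dti), proteins = proteinIds(dti),
                            nPerSet = NULL) {
    pt <- pairs(dti)
    nPos <- if (is.null(nPerSet)) nrow(pt) else as.integer(nPerSet)
    nAll <- length(drugs) * length(proteins)
    posIdx <- (match(pt$drug, drugs) - 1) * length(proteins) +
        match(pt$protein, proteins)
    posIdx <- posIdx[!is.na(posIdx)]
    nFree <- nAll - length(posIdx)
    if (nFree < nPos)
        stop(sprintf("only %d non-positive combinations available, need %d",
                     nFree, nPos))
    freeIdx <- setdiff(seq_len(nAll), posIdx)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(rngSeed)
    lapply(seq_len(nSets), function(s) {
        pick <- sample(freeIdx, nPos)
        data.frame(drug = drugs[(pick - 1) %/% length(proteins) + 1],
                   protein = proteins[(pick - 1) %% length(proteins) + 1],
                   stringsAsFactors = FALSE)
    })
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Build a labelled PairDataset with replicate negative sets
#'
#' Stacks the positive pairs (label 1, set index 0) and `nSets` replicate
#' negative samples (label 0, set index 1..nSets) into one dataset.
#'
#' @inheritParams sampleNegatives
#' @param drugF,protF feature matrices passed to [makePairVectors()].
#' @return A [PairDataset-class].
#' @export
buildPairDataset <- function(dti, drugF, protF, nSets = 20, rngSeed = 1,
                             drugs = drugIds(dti),
                             proteins = proteinIds(dti)) {
    pos <- makePairVectors(pairs(dti), drugF, protF)
    negs <- sampleNegatives(dti, nSets = nSets, rngSeed = rngSeed,
                            drugs = drugs, proteins = proteins)
    negParts <- lapply(negs, makePairVectors, drugF = drugF, protF = protF)
    X <- do.call(rbind, c(list(pos$X), lapply(negParts, `[[`, "X")))
    pairIds <- do.call(rbind, c(list(pos$pairIds),
                                lapply(negParts, `[[`, "pairIds")))
    nPos <- nrow(pos$X)
    y <- c(rep(1L, nPos), rep(0L, nPos * nSets))
    setIdx <- c(rep(0L, nPos), rep(seq_len(nSets), each = nPos))
    new("PairDataset", pairIds = pairIds, X = X, y = y,
        negativeSet = setIdx, drugWidth = ncol(featureValues(drugF)))
}

#' Cubic (Minkowski p = 3) distance
#'
#' \eqn{d(x, y) = (\sum_i |x_i - y_i|^3)^{1/3}}. The cubic exponent
#' accentuates coordinates with large differences, which amplifies the
#' contrast created by network weighting of the features.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar; 0 iff `x == y`.
#' @examples
#' cubicDistance(c(0, 0), c(1, 1))   # 2^(1/3)
#' @export
cubicDistance <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length")
    sum(abs(x - y)^3)^(1 / 3)
}

## All pairwise cubic distances between rows of Q (queries) and rows of X
## (training). Chunked over queries to bound memory.
.cubicCrossDistance <- function(Q, X, chunk = 256L) {
    n <- nrow(Q)
    out <- matrix(0, n, nrow(X))
    for (s in seq(1, n, by = chunk)) {
        e <- min(s + chunk - 1L, n)
        block <- Q[s:e, , drop = FALSE]
        ## |q - x|^3 summed over features, per query/train pair
        d3 <- vapply(seq_len(nrow(X)), function(j) {
            rowSums(abs(block - matrix(X[j, ], nrow(block), ncol(X),
                                       byrow = TRUE))^3)
        }, numeric(nrow(block)))
        out[s:e, ] <- matrix(d3, nrow = nrow(block))^(1 / 3)
    }
    out
}

#' Fit the cubic-distance kNN classifier
#'
#' Exact (brute-force) k-nearest-neighbour model under the Minkowski
#' distance with exponent 3. "Fitting" stores the training data; all work
#' happens at scoring time.
#'
#' By default every feature is standardized to the training mean and
#' standard deviation before distances are computed (queries are
#' standardized with the stored training statistics at scoring time), the
#' usual preset for distance-exponent kNN classifiers. Without it the pair
#' vector's large-magnitude descriptor block (distribution positions in
#' percent) swamps the binary fingerprint block under the cubic exponent.
#' Constant features get unit scale.
#'
#' @param train A [PairDataset-class] (or any object with matrix `X` and 0/1
#'   labels `y` when given as a list).
#' @param k number of neighbours; 1 <= k <= number of training rows.
#'   Default 10.
#' @param standardize standardize features to training mean/sd
#'   (default TRUE).
#' @return A [KNNModel-class].
#' @export
knnFit <- function(train, k = 10, standardize = TRUE) {
    if (is(train, "PairDataset")) {
        X <- train@X; y <- train@y
    } else {
        X <- train$X; y <- as.integer(train$y)
    }
    if (k > nrow(X))
        stop(sprintf("k = %d exceeds training size %d", k, nrow(X)))
    if (standardize) {
        ctr <- colMeans(X)
        scl <- apply(X, 2, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        X <- scale(X, center = ctr, scale = scl)
        attr(X, "scaled:center") <- NULL
        attr(X, "scaled:scale") <- NULL
        new("KNNModel", X = X, y = y, k = as.integer(k), exponent = 3,
            center = ctr, scale = scl)
    } else {
        new("KNNModel", X = X, y = y, k = as.integer(k), exponent = 3)
    }
}

#' Score queries with a fitted kNN model
#'
#' For each query row, finds the k training rows nearest under the cubic
#' distance and returns the fraction of positive labels among them -- a
#' score in [0, 1]. Distance ties at the k-th neighbour are broken by
#' training-row order (stable sort), so scores are invariant to permuting
#' the training rows.
#'
#' @param model A [KNNModel-class].
#' @param X query matrix with the training feature width.
#' @return numeric scores in [0, 1], one per query row.
#' @export
knnScore <- function(model, X) {
    X <- as.matrix(X)
    if (ncol(X) != ncol(model@X))
        stop(sprintf("query width %d does not match training width %d",
                     ncol(X), ncol(model@X)))
    if (length(model@center)) {
        X <- scale(X, center = model@center, scale = model@scale)
        attr(X, "scaled:center") <- NULL
        attr(X, "scaled:scale") <- NULL
    }
    D <- .cubicCrossDistance(X, model@X)
    apply(D, 1, function(d) {
        nn <- order(d)[seq_len(model@k)]   # order() is stable: ties by row
        mean(model@y[nn] == 1L)
    })
}

#' Classify scored pairs at a threshold
#'
#' @param scores numeric scores from [knnScore()].
#' @param threshold decision threshold; default 0.62, the operating point
#'   used for reporting positive predictions (headline evaluation is
#'   threshold-free AUC).
#' @return integer 0/1 labels.
#' @export
knnClassify <- function(scores, threshold = 0.62) {
    as.integer(scores >= threshold)
}
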