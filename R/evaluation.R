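#' @include dti-model.R
NULL

#' ROC curve and AUC
#'
#' Threshold-free evaluation of scores against binary labels. The AUC is
#' computed as the Mann-Whitney statistic (probability that a random
#' positive outscores a random negative, ties counted half), which equals
#' the trapezoidal area under the ROC curve with midpoint tie handling.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return list with `auc` and `rocPoints`, a data.frame of (fpr, tpr)
#'   starting at (0, 0) and ending at (1, 1), both coordinates
#'   non-decreasing.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc   # 0.75
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(scores) != length(labels))
        stop("scores and labels must have equal length")
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0 || nNeg == 0)
        stop("both classes must be present to compute an ROC curve")
    r <- rank(scores)                      # average ranks handle ties
    auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]; sc <- scores[ord]
    tp <- cumsum(lab == 1L); fp <- cumsum(lab == 0L)
    last <- c(sc[-1] != sc[-length(sc)], TRUE)   # one point per threshold
    roc <- data.frame(fpr = c(0, fp[last] / nNeg),
                      tpr = c(0, tp[last] / nPos))
    list(auc = auc, rocPoints = roc)
}

#' Stratified cross-validation of the cubic kNN
#'
#' Splits a labelled dataset into stratified folds (class proportions
#' preserved), trains the cubic-distance kNN on the complement of each fold
#' and scores the fold, reporting per-fold and mean AUC. When the dataset
#' carries several replicate negative sets, each set is evaluated separately
#' (positives + that set's negatives) and the per-set mean CV AUCs are
#' returned, matching the replicate-negative-set reporting convention.
#'
#' @param dataset A [PairDataset-class].
#' @param nFolds number of folds (default 10).
#' @param rngSeed seed controlling the fold assignment.
#' @param k kNN neighbour count (default 10).
#' @return list with `aucPerNegativeSet` (named by set; one entry when the
#'   dataset has a single set), `foldAuc` (per set, per fold), `meanAuc`,
#'   `sdAuc`, and the configuration used.
#' @export
crossValidate <- function(dataset, nFolds = 10, rngSeed = 1, k = 10) {
    if (nFolds < 2) stop("nFolds must be >= 2")
    sets <- sort(unique(dataset@negativeSet[dataset@y == 0L]))
    if (!length(sets)) stop("dataset has no negatives")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(rngSeed)
    posIdx <- which(dataset@y == 1L)
    perSet <- lapply(sets, function(s) {
        idx <- c(posIdx, which(dataset@y == 0L & dataset@negativeSet == s))
        X <- dataset@X[idx, , drop = FALSE]
        y <- dataset@y[idx]
        fold <- integer(length(y))
        for (cls in c(0L, 1L)) {          # stratified assignment
            w <- which(y == cls)
            fold[w] <- sample(rep_len(seq_len(nFolds), length(w)))
        }
        vapply(seq_len(nFolds), function(f) {
            tr <- fold != f
            if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
                stop("a fold lost one of the classes; use fewer folds")
            m <- knnFit(list(X = X[tr, , drop = FALSE], y = y[tr]),
                        k = min(k, sum(tr)))
            rocAuc(knnScore(m, X[!tr, , drop = FALSE]), y[!tr])$auc
        }, 0)
    })
    aucSet <- vapply(perSet, mean, 0)
    names(aucSet) <- paste0("set", sets)
    list(aucPerNegativeSet = aucSet, foldAuc = perSet,
         meanAuc = mean(aucSet), sdAuc = stats::sd(aucSet),
         config = list(nFolds = nFolds, rngSeed = rngSeed, k = k))
}

#' Paired t-test between two per-replicate AUC series
#'
#' Two-sided paired t-test over AUCs paired by negative-set replicate, the
#' test used to compare weighting schemes (e.g. restart-walk weighting vs
#' guilt-by-association).
#'
#' @param aucA,aucB equal-length numeric vectors (length >= 2), paired by
#'   replicate index.
#' @return list with `t`, `p`, `meanDiff` and `df`.
#' @export
pairedTTest <- function(aucA, aucB) {
    if (length(aucA) != length(aucB) || length(aucA) < 2)
        stop("need two equal-length series of length >= 2")
    d <- aucA - aucB
    if (stats::sd(d) == 0)
        stop("zero variance of paired differences; t-test undefined")
    ht <- stats::t.test(aucA, aucB, paired = TRUE)
    list(t = unname(ht$statistic), p = ht$p.value,
         meanDiff = unname(ht$estimate), df = unname(ht$parameter))
}
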