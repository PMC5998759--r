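#' @include evaluation.R propagation.R net-io.R descriptors.R
NULL

#' Network-weight drug and protein feature matrices
#'
#' Applies the chosen weighting scheme to both feature matrices: restart
#' walk ("rwr", affinity-matrix product on the DDI network for drugs and the
#' PPI network for proteins), one-hop guilt-by-association ("gba"), or none.
#' Entities absent from a network are kept with their original features (a
#' feature row without a network row cannot be smoothed).
#'
#' @param drugF,protF raw [FeatureMatrix-class] objects.
#' @param ddi,ppi [InteractionNetwork-class] objects.
#' @param weighting "rwr", "gba" or "none".
#' @param config [RWRConfig-class] for the restart walk.
#' @param gbaSelfWeight self weight for the guilt-by-association mixture.
#' @return list with weighted `drugF` and `protF`.
#' @export
weightFeaturePair <- function(drugF, protF, ddi, ppi,
                              weighting = c("rwr", "gba", "none"),
                              config = rwrConfig(), gbaSelfWeight = 1) {
    weighting <- match.arg(weighting)
    smooth1 <- function(F, net) {
        ids <- intersect(nodeIds(net), entityIds(F))
        if (!length(ids) || weighting == "none") return(F)
        sub <- .induceSubnetwork(net, ids)
        out <- featureValues(F)
        if (weighting == "rwr") {
            W <- affinityMatrix(sub, config)
            out[entityIds(W), ] <- featureValues(weightFeatures(W, F))
        } else {
            G <- gbaWeighting(sub, F, includeSelfWeight = gbaSelfWeight)
            out[entityIds(G), ] <- featureValues(G)
        }
        featureMatrix(out)
    }
    list(drugF = smooth1(drugF, ddi), protF = smooth1(protF, ppi))
}

## Subnetwork induced on a node subset (keeps all of `ids`, including nodes
## that lose every edge).
.induceSubnetwork <- function(net, ids) {
    et <- edges(net)
    keep <- et$from %in% ids & et$to %in% ids
    interactionNetwork(et$from[keep], et$to[keep], et$weight[keep],
                       nodes = ids)
}

#' Run the full prediction pipeline and evaluate on held-out pairs
#'
#' End-to-end protocol: weight the feature matrices by the chosen scheme,
#' build training pair vectors from the training positives plus `nSets`
#' replicate negative samples, fit one cubic kNN per negative set, and score
#' a held-out test set (held-out positives plus a test negative sample of
#' equal size drawn from combinations that are positive in neither split).
#' Reports one test AUC per negative set, their mean and sd, and the ROC of
#' the set-averaged scores.
#'
#' @param dtiTrain,dtiTest [BipartiteDTI-class] training and held-out
#'   positives (disjoint).
#' @param drugF,protF raw feature matrices covering all entities involved.
#' @param ddi,ppi interaction networks used for weighting.
#' @param weighting "rwr", "gba" or "none".
#' @param config [RWRConfig-class]; restart probability defaults to 0.25.
#' @param gbaSelfWeight self weight for "gba".
#' @param nSets replicate negative sets (default 20).
#' @param knnK neighbours for the kNN (default 10).
#' @param rngSeed master seed for negative sampling (train and test).
#' @return list with `aucPerNegativeSet`, `meanAuc`, `sdAuc`, `rocPoints`
#'   (on set-averaged scores), `meanScores`, `testLabels`, and a `config`
#'   snapshot.
#' @export
runPipeline <- function(dtiTrain, dtiTest, drugF, protF, ddi, ppi,
                        weighting = c("rwr", "gba", "none"),
                        config = rwrConfig(), gbaSelfWeight = 1,
                        nSets = 20, knnK = 10, rngSeed = 1) {
    weighting <- match.arg(weighting)
    wf <- weightFeaturePair(drugF, protF, ddi, ppi, weighting = weighting,
                            config = config, gbaSelfWeight = gbaSelfWeight)
    train <- buildPairDataset(dtiTrain, wf$drugF, wf$protF, nSets = nSets,
                              rngSeed = rngSeed)
    ## held-out test set: positives + an equal-size negative sample drawn
    ## over the held-out entity universe (test drugs x test proteins,
    ## excluding positives of either split), so both test classes face the
    ## same entity frequencies and only the drug-protein match carries signal
    allPos <- bipartiteDTI(c(pairs(dtiTrain)$drug, pairs(dtiTest)$drug),
                           c(pairs(dtiTrain)$protein, pairs(dtiTest)$protein))
    nTestPos <- nrow(pairs(dtiTest))
    testNeg <- sampleNegatives(allPos, nSets = 1, rngSeed = rngSeed + 10007L,
                               drugs = drugIds(dtiTest),
                               proteins = proteinIds(dtiTest),
                               nPerSet = nTestPos)[[1]]
    testPos <- makePairVectors(pairs(dtiTest), wf$drugF, wf$protF)
    testNegV <- makePairVectors(testNeg, wf$drugF, wf$protF)
    Xtest <- rbind(testPos$X, testNegV$X)
    yTest <- c(rep(1L, nrow(testPos$X)), rep(0L, nrow(testNegV$X)))
    sets <- seq_len(nSets)
    scoreMat <- vapply(sets, function(s) {
        idx <- which(train@negativeSet %in% c(0L, s))
        m <- knnFit(list(X = train@X[idx, , drop = FALSE],
                         y = train@y[idx]), k = knnK)
        knnScore(m, Xtest)
    }, numeric(nrow(Xtest)))
    aucSet <- apply(scoreMat, 2, function(sc) rocAuc(sc, yTest)$auc)
    names(aucSet) <- paste0("set", sets)
    meanScores <- rowMeans(scoreMat)
    roc <- rocAuc(meanScores, yTest)
    list(aucPerNegativeSet = aucSet, meanAuc = mean(aucSet),
         sdAuc = stats::sd(aucSet), rocPoints = roc$rocPoints,
         meanScores = meanScores, testLabels = yTest,
         config = list(weighting = weighting, restartC = config@restartC,
                       gbaSelfWeight = gbaSelfWeight, nSets = nSets,
                       knnK = knnK, rngSeed = rngSeed))
}

#' Sweep the restart probability
#'
#' Re-runs weighting, training and evaluation for each restart probability
#' in `cGrid` and tabulates training AUC (stratified cross-validation on the
#' first negative set) and held-out test AUC (mean over negative sets). At
#' c = 1 the affinity matrix is the identity, so that row reproduces the
#' unweighted model exactly.
#'
#' @param cGrid numeric vector of restart probabilities in (0, 1].
#' @param dtiTrain,dtiTest,drugF,protF,ddi,ppi as in [runPipeline()].
#' @param nSets,knnK,rngSeed as in [runPipeline()].
#' @param cvFolds folds for the training-side cross-validation (default 5).
#' @return data.frame with columns `c`, `trainAuc`, `testAuc`, sorted by
#'   `c`.
#' @export
sweepRestartC <- function(cGrid, dtiTrain, dtiTest, drugF, protF, ddi, ppi,
                          nSets = 20, knnK = 10, rngSeed = 1, cvFolds = 5) {
    stopifnot(all(cGrid > 0 & cGrid <= 1))
    cGrid <- sort(cGrid)
    rows <- lapply(cGrid, function(cc) {
        cfg <- rwrConfig(restartC = cc)
        res <- runPipeline(dtiTrain, dtiTest, drugF, protF, ddi, ppi,
                           weighting = "rwr", config = cfg, nSets = nSets,
                           knnK = knnK, rngSeed = rngSeed)
        wf <- weightFeaturePair(drugF, protF, ddi, ppi, weighting = "rwr",
                                config = cfg)
        tr <- buildPairDataset(dtiTrain, wf$drugF, wf$protF, nSets = 1,
                               rngSeed = rngSeed)
        cv <- crossValidate(tr, nFolds = cvFolds, rngSeed = rngSeed, k = knnK)
        data.frame(c = cc, trainAuc = cv$meanAuc, testAuc = res$meanAuc)
    })
    do.call(rbind, rows)
}
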