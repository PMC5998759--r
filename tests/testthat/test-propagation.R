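test_that("adjacency normalization is column-stochastic on worked examples", {
    two <- interactionNetwork("A", "B")
    expect_equal(as.matrix(normalizeAdjacency(two)),
                 matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"),
                                                          c("A", "B"))))
    ## star: center "c" with unit leaves l1..l3
    star <- interactionNetwork(rep("c", 3), c("l1", "l2", "l3"))
    At <- as.matrix(normalizeAdjacency(star))
    expect_equal(unname(At[c("l1", "l2", "l3"), "c"]), rep(1 / 3, 3))
    expect_equal(unname(At["c", c("l1", "l2", "l3")]), rep(1, 3))
    ## isolated node: all-zero column
    iso <- interactionNetwork("A", "B", nodes = c("A", "B", "Z"))
    expect_equal(sum(normalizeAdjacency(iso)[, "Z"]), 0)
})

test_that("restart walk worked examples hold", {
    net <- interactionNetwork("A", "B")
    r <- rwr(net, "A", rwrConfig(restartC = 0.5))
    expect_equal(unname(r), c(2 / 3, 1 / 3), tolerance = 1e-9)
    ## c = 1: restart dominates, r = q
    r1 <- rwr(net, "A", rwrConfig(restartC = 1))
    expect_equal(unname(r1), c(1, 0))
    ## isolated seed: point mass
    iso <- interactionNetwork("A", "B", nodes = c("A", "B", "Z"))
    rz <- rwr(iso, "Z", rwrConfig(restartC = 0.3))
    expect_equal(unname(rz), c(0, 0, 1))
    expect_error(rwr(net, "nope"), "not a node")
})

test_that("iterative walk matches the closed form on random graphs", {
    set.seed(21)
    for (rep in 1:30) {
        net <- randomNetwork(sample(4:20, 1), pEdge = 0.35)
        seed <- sample(nodeIds(net), 1)
        cc <- sample(c(0.1, 0.25, 0.5, 0.9), 1)
        it <- rwr(net, seed, rwrConfig(restartC = cc))
        cf <- rwrClosedForm(net, seed, rwrConfig(restartC = cc))
        expect_equal(it, cf, tolerance = 1e-8)
    }
})

test_that("affinity rows are distributions with self-affinity >= c", {
    set.seed(33)
    for (cc in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
        net <- randomNetwork(12, pEdge = 0.3)
        W <- affinityMatrix(net, rwrConfig(restartC = cc))
        v <- featureValues(W)
        expect_true(all(v >= 0))
        expect_equal(unname(rowSums(v)), rep(1, nrow(v)), tolerance = 1e-6)
        expect_true(all(diag(v) >= cc - 1e-9))
    }
})

test_that("self-affinity is non-decreasing in the restart probability", {
    set.seed(17)
    for (rep in 1:5) {
        net <- randomNetwork(10, pEdge = 0.4)
        seed <- sample(nodeIds(net), 1)
        selfAff <- vapply(seq(0.1, 0.9, by = 0.2), function(cc)
            rwr(net, seed, rwrConfig(restartC = cc))[seed], 0)
        expect_true(all(diff(selfAff) >= -1e-9))
    }
})

test_that("a symmetric graph yields a symmetric affinity matrix and c=1 the identity", {
    net <- interactionNetwork("A", "B")
    W <- featureValues(affinityMatrix(net, rwrConfig(restartC = 0.4)))
    expect_equal(W, t(W), tolerance = 1e-9)
    Wid <- featureValues(affinityMatrix(net, rwrConfig(restartC = 1)))
    expect_equal(unname(Wid), diag(2))
})

test_that("affinity weighting mixes features as a convex combination", {
    net <- interactionNetwork("A", "B")
    F <- featureMatrix(matrix(c(1, 0, 0, 2), 2, 2,
                              dimnames = list(c("A", "B"), c("f1", "f2"))))
    ## identity weighting at c = 1
    Wid <- affinityMatrix(net, rwrConfig(restartC = 1))
    expect_equal(featureValues(weightFeatures(Wid, F)), featureValues(F))
    ## c = 0.5 two-node closed form: row A = 2/3 fA + 1/3 fB
    W <- affinityMatrix(net, rwrConfig(restartC = 0.5))
    got <- featureValues(weightFeatures(W, F))
    expect_equal(unname(got["A", ]), c(2 / 3, 2 / 3), tolerance = 1e-9)
    expect_equal(unname(got["B", ]), c(1 / 3, 4 / 3), tolerance = 1e-9)
    ## convexity: weighted values stay inside the component's feature range
    set.seed(12)
    net2 <- randomNetwork(10, pEdge = 0.5)
    F2 <- featureMatrix(matrix(stats::rnorm(10 * 4), 10, 4,
                               dimnames = list(nodeIds(net2),
                                               paste0("f", 1:4))))
    W2 <- affinityMatrix(net2, rwrConfig(restartC = 0.25))
    got2 <- featureValues(weightFeatures(W2, F2))
    for (j in 1:4) {
        expect_true(all(got2[, j] >= min(featureValues(F2)[, j]) - 1e-9))
        expect_true(all(got2[, j] <= max(featureValues(F2)[, j]) + 1e-9))
    }
    ## entities missing from the feature matrix are an error
    expect_error(weightFeatures(W2, F), "missing")
})

test_that("guilt-by-association weighting mixes direct neighbours only", {
    F <- featureMatrix(matrix(c(1, 0, 0, 0,
                                0, 2, 0, 0), 4, 2,
                              dimnames = list(c("c", "l1", "l2", "l3"),
                                              c("f1", "f2"))))
    ## isolated node keeps its features
    iso <- interactionNetwork("c", "l1", nodes = c("c", "l1", "l2", "l3"))
    gi <- featureValues(gbaWeighting(iso, F))
    expect_equal(gi["l2", ], featureValues(F)["l2", ])
    ## one unit-weight neighbour with self-weight 1: mean of the two rows
    expect_equal(unname(gi["c", ]),
                 unname((featureValues(F)["c", ] +
                         featureValues(F)["l1", ]) / 2))
    ## star: center mixes all leaves; leaves mix only the center
    star <- interactionNetwork(rep("c", 3), c("l1", "l2", "l3"))
    gs <- featureValues(gbaWeighting(star, F))
    expect_equal(unname(gs["c", ]),
                 unname((featureValues(F)["c", ] + featureValues(F)["l1", ] +
                         featureValues(F)["l2", ] +
                         featureValues(F)["l3", ]) / 4))
    expect_equal(unname(gs["l1", ]),
                 unname((featureValues(F)["l1", ] +
                         featureValues(F)["c", ]) / 2))
})

test_that("restart weighting contracts feature distances across edges", {
    set.seed(99)
    w <- generateWorld(nModules = 2, proteinsPerModule = 10,
                       drugsPerModule = 4, rngSeed = 5)
    F <- w@fingerprints
    W <- affinityMatrix(w@ddi, rwrConfig(restartC = 0.25))
    Fw <- weightFeatures(W, F)
    et <- edges(w@ddi)
    raw <- mean(vapply(seq_len(nrow(et)), function(i)
        sqrt(sum((featureValues(F)[et$from[i], ] -
                  featureValues(F)[et$to[i], ])^2)), 0))
    wtd <- mean(vapply(seq_len(nrow(et)), function(i)
        sqrt(sum((featureValues(Fw)[et$from[i], ] -
                  featureValues(Fw)[et$to[i], ])^2)), 0))
    expect_lt(wtd, raw)
})
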