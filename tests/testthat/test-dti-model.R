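drugFix <- featureMatrix(matrix(c(1, 0, 0,
                                  0, 1, 0), 2, 3, byrow = TRUE,
                                dimnames = list(c("d1", "d2"),
                                                paste0("b", 1:3))))
protFix <- featureMatrix(matrix(c(0.1, 0.2,
                                  0.3, 0.4), 2, 2, byrow = TRUE,
                                dimnames = list(c("p1", "p2"),
                                                paste0("f", 1:2))))

test_that("pair vectors concatenate drug block then protein block", {
    pv <- makePairVectors(data.frame(drug = c("d1", "d1", "d2"),
                                     protein = c("p1", "p2", "p2")),
                          drugFix, protFix)
    expect_equal(dim(pv$X), c(3L, 5L))
    expect_equal(unname(pv$X[1, ]), c(1, 0, 0, 0.1, 0.2))
    ## two pairs sharing a drug have identical drug blocks
    expect_equal(pv$X[1, 1:3], pv$X[2, 1:3])
    ## zero features give a zero pair vector
    zf <- featureMatrix(matrix(0, 1, 3, dimnames = list("d1", paste0("b", 1:3))))
    zp <- featureMatrix(matrix(0, 1, 2, dimnames = list("p1", paste0("f", 1:2))))
    expect_equal(unname(makePairVectors(data.frame(drug = "d1",
                                                   protein = "p1"),
                                        zf, zp)$X[1, ]), rep(0, 5))
})

test_that("missing feature rows error in strict mode and drop in lenient mode", {
    df <- data.frame(drug = c("d1", "dX"), protein = c("p1", "p1"))
    expect_error(makePairVectors(df, drugFix, protFix), "dX/p1")
    expect_warning(pv <- makePairVectors(df, drugFix, protFix,
                                         strict = FALSE), "dropping 1")
    expect_equal(nrow(pv$X), 1)
})

test_that("negative sampling avoids positives and is seed-reproducible", {
    ## 2 x 2 grid with 2 positives: the negative set is forced
    dti <- bipartiteDTI(c("d1", "d2"), c("p1", "p2"))
    negs <- sampleNegatives(dti, nSets = 3, rngSeed = 4)
    for (ns in negs) {
        key <- sort(paste(ns$drug, ns$protein))
        expect_equal(key, c("d1 p2", "d2 p1"))
    }
    ## disjointness from positives over many draws
    set.seed(6)
    dti2 <- bipartiteDTI(sprintf("d%d", sample(8, 25, TRUE)),
                         sprintf("p%d", sample(8, 25, TRUE)))
    posKey <- paste(pairs(dti2)$drug, pairs(dti2)$protein)
    negs2 <- sampleNegatives(dti2, nSets = 50, rngSeed = 11)
    for (ns in negs2) {
        expect_equal(nrow(ns), nrow(pairs(dti2)))
        expect_length(intersect(paste(ns$drug, ns$protein), posKey), 0)
    }
    ## reproducibility
    a <- sampleNegatives(dti2, nSets = 2, rngSeed = 7)
    b <- sampleNegatives(dti2, nSets = 2, rngSeed = 7)
    d <- sampleNegatives(dti2, nSets = 2, rngSeed = 8)
    expect_identical(a, b)
    expect_false(identical(a, d))
    ## infeasible request
    dense <- bipartiteDTI(c("d1", "d1"), c("p1", "p2"))
    expect_error(sampleNegatives(dense), "non-positive combinations")
})

test_that("pair datasets carry balanced replicate negative sets", {
    drugF3 <- featureMatrix(matrix(rep(diag(3), 1), 3, 3,
                                   dimnames = list(c("d1", "d2", "d3"),
                                                   paste0("b", 1:3))))
    protF3 <- featureMatrix(matrix(seq_len(6) / 10, 3, 2,
                                   dimnames = list(c("p1", "p2", "p3"),
                                                   paste0("f", 1:2))))
    dti <- bipartiteDTI(c("d1", "d1", "d2", "d3"),
                        c("p1", "p2", "p2", "p3"))
    ds <- buildPairDataset(dti, drugF3, protF3, nSets = 4, rngSeed = 2)
    expect_equal(sum(ds@y == 1L), 4)
    expect_equal(sum(ds@y == 0L), 16)
    for (s in 1:4)
        expect_equal(sum(ds@negativeSet == s), 4)
    expect_equal(ncol(ds@X), 5)
    expect_equal(ds@drugWidth, 3L)
})

test_that("cubic distance evaluates the Minkowski p=3 formula", {
    expect_equal(cubicDistance(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(cubicDistance(0, 2), 2)
    expect_equal(cubicDistance(c(0, 0), c(1, 1)), 2^(1 / 3))
    expect_equal(cubicDistance(c(0, 0), c(3, 4)), (27 + 64)^(1 / 3))
    ## symmetry
    set.seed(1)
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(cubicDistance(x, y), cubicDistance(y, x))
    expect_error(cubicDistance(1:3, 1:4), "equal length")
})

test_that("kNN scoring matches a brute-force scan", {
    set.seed(14)
    n <- 150
    X <- matrix(rnorm(n * 8), n, 8)
    y <- sample(0:1, n, TRUE)
    Q <- matrix(rnorm(12 * 8), 12, 8)
    for (k in c(1, 5, 11)) {
        m <- knnFit(list(X = X, y = y), k = k, standardize = FALSE)
        expect_equal(knnScore(m, Q), bruteForceKnnScore(X, y, Q, k))
    }
    ## standardized model: oracle on pre-standardized data agrees
    m <- knnFit(list(X = X, y = y), k = 7, standardize = TRUE)
    Xs <- scale(X)
    Qs <- scale(Q, center = attr(Xs, "scaled:center"),
                scale = attr(Xs, "scaled:scale"))
    expect_equal(knnScore(m, Q),
                 bruteForceKnnScore(Xs, y, Qs, 7),
                 tolerance = 1e-12)
})

test_that("kNN degenerate and separable cases behave", {
    set.seed(3)
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(c(1L, 0L), 10)
    m1 <- knnFit(list(X = X, y = y), k = 1, standardize = FALSE)
    expect_equal(knnScore(m1, X[1, , drop = FALSE]), 1)   # own row, k = 1
    expect_error(knnFit(list(X = X, y = y), k = 21), "exceeds")
    ## two well-separated clusters: held-out accuracy ~ 1
    Xc <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
    yc <- rep(c(0L, 1L), each = 50)
    tr <- c(1:40, 51:90); te <- setdiff(1:100, tr)
    m <- knnFit(list(X = Xc[tr, ], y = yc[tr]), k = 5)
    acc <- mean((knnScore(m, Xc[te, ]) >= 0.5) == (yc[te] == 1L))
    expect_gte(acc, 0.95)
})

test_that("kNN scores are invariant to training-row permutation", {
    set.seed(10)
    X <- matrix(rnorm(60 * 4), 60, 4)    # continuous: ties have measure zero
    y <- sample(0:1, 60, TRUE)
    Q <- matrix(rnorm(8 * 4), 8, 4)
    m <- knnFit(list(X = X, y = y), k = 9)
    perm <- sample(60)
    mp <- knnFit(list(X = X[perm, ], y = y[perm]), k = 9)
    expect_equal(knnScore(m, Q), knnScore(mp, Q))
})

test_that("threshold classification uses the configured operating point", {
    expect_equal(knnClassify(c(0.9, 0.62, 0.5)), c(1L, 1L, 0L))
    expect_equal(knnClassify(c(0.9, 0.5), threshold = 0.4), c(1L, 1L))
})
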