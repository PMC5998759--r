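# Shared fixtures: tiny deterministic inputs built in code.

writeTempTSV <- function(lines, ext = ".tsv") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

# Small PPI edge list on the 0-1000 confidence scale.
tinyPPIFile <- function() {
    writeTempTSV(c("P1\tP2\t900", "P2\tP3\t850", "P3\tP4\t799",
                   "P1\tP4\t800"))
}

# Random connected-ish weighted graph for propagation tests.
randomNetwork <- function(n, pEdge = 0.4) {
    ids <- sprintf("n%02d", seq_len(n))
    from <- character(0); to <- character(0)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (stats::runif(1) < pEdge) {
            from <- c(from, ids[i]); to <- c(to, ids[j])
        }
    }
    interactionNetwork(from, to, weight = stats::runif(length(from), 0.5, 1),
                       nodes = ids)
}

randomSequence <- function(L) {
    paste(sample(rwrDTI:::AA20, L, replace = TRUE), collapse = "")
}

# Direct-summation reference for the autocorrelation formulas, written
# independently of the package implementation.
referenceAutocorrelation <- function(seq, scale, d, kind) {
    P <- scale[strsplit(seq, "")[[1]]]
    L <- length(P)
    Pbar <- mean(P)
    i <- seq_len(L - d)
    switch(kind,
        "moreau-broto" = sum(P[i] * P[i + d]) / (L - d),
        "moran" = (sum((P[i] - Pbar) * (P[i + d] - Pbar)) / (L - d)) /
            (sum((P - Pbar)^2) / L),
        "geary" = (sum((P[i] - P[i + d])^2) / (2 * (L - d))) /
            (sum((P - Pbar)^2) / (L - 1)))
}

# Brute-force kNN scorer: per query, full distance scan with cubicDistance.
bruteForceKnnScore <- function(Xtrain, y, Xquery, k) {
    apply(Xquery, 1, function(q) {
        d <- apply(Xtrain, 1, function(r) cubicDistance(q, r))
        mean(y[order(d)[seq_len(k)]] == 1L)
    })
}

# Concordant-pair AUC with half credit for ties.
bruteForceAuc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
}
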