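#' @include methods.R
NULL

## Canonical amino-acid alphabet, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Load the bundled amino-acid property scales
#'
#' Eight physicochemical scales (hydrophobicity, average flexibility,
#' polarizability, free energy of solution in water, accessible surface
#' area, residue volume, steric parameter, relative mutability), one value
#' per canonical amino acid, taken from the AAindex database. Used by the
#' three autocorrelation descriptor families (8 scales x 30 lags = 240
#' dimensions per family). Any user matrix with the same shape (rows =
#' scales, columns = the 20 amino acids) can be substituted.
#'
#' @param standardize centre and scale each row to mean 0 / sd 1 over the 20
#'   amino acids (the "normalized" in normalized Moreau-Broto); default TRUE.
#' @return numeric matrix, scales x 20 amino acids.
#' @export
defaultPropertyScales <- function(standardize = TRUE) {
    path <- system.file("extdata", "aa_property_scales.tsv",
                        package = "rwrDTI", mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, AA20])
    rownames(m) <- df$scale
    if (standardize) m <- standardizeScales(m)
    m
}

#' Standardize property scales over the 20 amino acids
#'
#' @param scales matrix with 20 columns (amino acids).
#' @return matrix with each row centred to mean 0 and scaled to unit
#'   standard deviation (denominator n = 20).
#' @export
standardizeScales <- function(scales) {
    stopifnot(ncol(scales) == 20)
    t(apply(scales, 1, function(v) {
        s <- sqrt(mean((v - mean(v))^2))
        (v - mean(v)) / s
    }))
}

#' Load the bundled CTD attribute groupings
#'
#' Seven physicochemical attributes, each partitioning the 20 amino acids
#' into 3 groups (the standard Dubchak groupings: hydrophobicity, normalized
#' van der Waals volume, polarity, polarizability, charge, secondary
#' structure, solvent accessibility).
#'
#' @return named list of 7 attributes; each element a list of 3 character
#'   vectors of residues.
#' @export
defaultCTDGroups <- function() {
    path <- system.file("extdata", "ctd_groups.tsv",
                        package = "rwrDTI", mustWork = TRUE)
    df <- utils::read.delim(path, colClasses = "character")
    out <- lapply(seq_len(nrow(df)), function(i) {
        g <- lapply(df[i, c("group1", "group2", "group3")],
                    function(s) strsplit(s, "")[[1]])
        names(g) <- c("g1", "g2", "g3")
        stopifnot(length(unlist(g)) == 20, !anyDuplicated(unlist(g)))
        g
    })
    names(out) <- df$attribute
    out
}

#' Sanitize a protein sequence
#'
#' Uppercases and removes non-canonical residue codes (B, J, O, U, X, Z and
#' anything outside the 20-letter alphabet) with a warning; in strict mode
#' non-canonical residues are an error instead.
#'
#' @param seq character scalar (or AAString) amino-acid sequence.
#' @param strict error instead of dropping non-canonical residues.
#' @return cleaned character scalar.
#' @export
sanitizeSequence <- function(seq, strict = FALSE) {
    s <- toupper(as.character(seq))
    chars <- strsplit(s, "")[[1]]
    ok <- chars %in% AA20
    if (any(!ok)) {
        if (strict)
            stop("non-canonical residues in sequence: ",
                 paste(unique(chars[!ok]), collapse = ", "))
        warning(sprintf("removed %d non-canonical residue(s): %s", sum(!ok),
                        paste(unique(chars[!ok]), collapse = ", ")))
    }
    paste(chars[ok], collapse = "")
}

#' Amino acid composition (20 dimensions)
#'
#' Frequency of each canonical residue, in fixed alphabetical order; sums
#' to 1 for any non-empty sequence.
#'
#' @param seq sanitized amino-acid sequence.
#' @return named numeric vector of length 20.
#' @export
aac <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    if (!length(chars)) stop("empty sequence")
    tab <- table(factor(chars, levels = AA20))
    v <- as.numeric(tab) / length(chars)
    names(v) <- paste0("AAC.", AA20)
    v
}

#' Dipeptide composition (400 dimensions)
#'
#' Frequency of each ordered residue pair among the L - 1 overlapping
#' dipeptides; sums to 1 for sequences of length >= 2.
#'
#' @param seq sanitized amino-acid sequence, length >= 2.
#' @return named numeric vector of length 400.
#' @export
dpc <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    if (L < 2) stop("dipeptide composition needs a sequence of length >= 2")
    dip <- paste0(chars[-L], chars[-1])
    levels <- as.vector(t(outer(AA20, AA20, paste0)))
    tab <- table(factor(dip, levels = levels))
    v <- as.numeric(tab) / (L - 1)
    names(v) <- paste0("DPC.", levels)
    v
}

#' Sequence autocorrelation descriptors
#'
#' Lagged autocorrelation of a per-residue physicochemical property P along
#' the sequence, for lags d = 1..maxlag. Three classical variants:
#' \describe{
#'   \item{moreau-broto}{normalized Moreau-Broto,
#'     \eqn{AC(d) = \frac{1}{L-d}\sum_{i=1}^{L-d} P_i P_{i+d}}.}
#'   \item{moran}{\eqn{I(d) = \frac{\frac{1}{L-d}\sum (P_i-\bar P)(P_{i+d}-\bar P)}
#'     {\frac{1}{L}\sum (P_i-\bar P)^2}}.}
#'   \item{geary}{\eqn{C(d) = \frac{\frac{1}{2(L-d)}\sum (P_i-P_{i+d})^2}
#'     {\frac{1}{L-1}\sum (P_i-\bar P)^2}}.}
#' }
#' \eqn{\bar P} is the mean of the property over the sequence. A sequence
#' with zero property variance (e.g. a homopolymer) returns 0 for Moran and
#' Geary lags instead of NaN, so downstream feature matrices stay finite.
#'
#' @param seq sanitized amino-acid sequence with length L > maxlag.
#' @param scale named numeric vector (one value per canonical amino acid) or
#'   a single row of [defaultPropertyScales()]; should be standardized.
#' @param maxlag largest lag; default 30.
#' @param kind one of "moreau-broto", "moran", "geary".
#' @return numeric vector of length `maxlag` (lags 1..maxlag).
#' @export
autocorrelation <- function(seq, scale, maxlag = 30,
                            kind = c("moreau-broto", "moran", "geary")) {
    kind <- match.arg(kind)
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    if (L <= maxlag)
        stop(sprintf("sequence length %d must exceed maxlag %d; lower maxlag",
                     L, maxlag))
    P <- unname(scale[chars])
    if (any(is.na(P))) stop("scale is missing values for some residues")
    Pbar <- mean(P)
    out <- numeric(maxlag)
    for (d in seq_len(maxlag)) {
        i <- seq_len(L - d)
        if (kind == "moreau-broto") {
            out[d] <- sum(P[i] * P[i + d]) / (L - d)
        } else if (kind == "moran") {
            denom <- sum((P - Pbar)^2) / L
            out[d] <- if (denom <= 0) 0 else
                (sum((P[i] - Pbar) * (P[i + d] - Pbar)) / (L - d)) / denom
        } else {
            denom <- sum((P - Pbar)^2) / (L - 1)
            out[d] <- if (denom <= 0) 0 else
                (sum((P[i] - P[i + d])^2) / (2 * (L - d))) / denom
        }
    }
    out
}

#' Composition/Transition/Distribution descriptors (147 dimensions)
#'
#' For each of 7 physicochemical attributes the residues are mapped to 3
#' groups, then:
#' \describe{
#'   \item{Composition (21)}{fraction of residues in each group.}
#'   \item{Transition (21)}{for each unordered group pair, the fraction of
#'     the L - 1 adjacent positions whose residues fall in the two distinct
#'     groups (either order).}
#'   \item{Distribution (105)}{for each group, the sequence positions (as a
#'     percentage of L, 1-based) of the first, 25\%, 50\%, 75\% and last
#'     occurrence of that group; groups absent from the sequence contribute
#'     zeros.}
#' }
#'
#' @param seq sanitized amino-acid sequence, length >= 2.
#' @param groups attribute groupings, default [defaultCTDGroups()].
#' @return named numeric vector of length 147 ordered C(21), T(21), D(105).
#' @export
ctd <- function(seq, groups = defaultCTDGroups()) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    if (L < 2) stop("CTD needs a sequence of length >= 2")
    comp <- numeric(0); tran <- numeric(0); dist <- numeric(0)
    for (attr in names(groups)) {
        g <- groups[[attr]]
        gid <- integer(L)
        for (k in 1:3) gid[chars %in% g[[k]]] <- k
        ## composition
        cv <- vapply(1:3, function(k) sum(gid == k) / L, 0)
        names(cv) <- paste0("CTDC.", attr, ".g", 1:3)
        comp <- c(comp, cv)
        ## transitions over adjacent positions
        a <- gid[-L]; b <- gid[-1]
        pairsKeys <- paste0(pmin(a, b), pmax(a, b))
        tv <- vapply(c("12", "13", "23"),
                     function(k) sum(pairsKeys == k) / (L - 1), 0)
        names(tv) <- paste0("CTDT.", attr, ".", c("g1g2", "g1g3", "g2g3"))
        tran <- c(tran, tv)
        ## distribution quantile positions
        for (k in 1:3) {
            pos <- which(gid == k)
            dv <- if (!length(pos)) rep(0, 5) else {
                n <- length(pos)
                idx <- pmax(1, c(1, ceiling(0.25 * n), ceiling(0.50 * n),
                                 ceiling(0.75 * n), n))
                100 * pos[idx] / L
            }
            names(dv) <- paste0("CTDD.", attr, ".g", k, ".",
                                c("first", "p25", "p50", "p75", "last"))
            dist <- c(dist, dv)
        }
    }
    c(comp, tran, dist)
}

#' Full protein primary-structure descriptor (1287 dimensions)
#'
#' Concatenates, in fixed order: amino acid composition (20), dipeptide
#' composition (400), normalized Moreau-Broto (240), Moran (240) and Geary
#' (240) autocorrelations over 8 property scales x 30 lags, and CTD
#' composition (21), transition (21) and distribution (105), for 1287
#' dimensions total. A pure function of the sequence.
#'
#' @param seq amino-acid sequence (sanitized internally).
#' @param scales standardized property-scale matrix, default
#'   [defaultPropertyScales()].
#' @param groups CTD groupings, default [defaultCTDGroups()].
#' @param maxlag autocorrelation maximum lag, default 30; sequence must be
#'   longer than this.
#' @param strict error (rather than warn) on non-canonical residues.
#' @return named numeric vector of length 1287.
#' @export
proteinDescriptor <- function(seq, scales = defaultPropertyScales(),
                              groups = defaultCTDGroups(), maxlag = 30,
                              strict = FALSE) {
    s <- sanitizeSequence(seq, strict = strict)
    prefix <- c("moreau-broto" = "NMB", "moran" = "MORAN", "geary" = "GEARY")
    acBlock <- function(kind) {
        unlist(lapply(rownames(scales), function(sc) {
            v <- autocorrelation(s, scales[sc, ], maxlag = maxlag, kind = kind)
            names(v) <- paste0(prefix[[kind]], ".", sc, ".lag",
                               seq_along(v))
            v
        }))
    }
    c(aac(s), dpc(s), acBlock("moreau-broto"), acBlock("moran"),
      acBlock("geary"), ctd(s, groups))
}

#' Descriptor block lengths
#'
#' The fixed widths of the descriptor blocks, in concatenation order.
#' @return named integer vector summing to 1287.
#' @export
descriptorBlockLengths <- function() {
    c(AAC = 20L, DPC = 400L, NMBroto = 240L, Moran = 240L, Geary = 240L,
      CTDC = 21L, CTDT = 21L, CTDD = 105L)
}

#' Descriptor matrix for a set of sequences
#'
#' @param seqs named character vector or `Biostrings::AAStringSet`.
#' @param ... passed to [proteinDescriptor()].
#' @return A [FeatureMatrix-class], proteins x 1287.
#' @export
proteinDescriptorMatrix <- function(seqs, ...) {
    seqChar <- stats::setNames(as.character(seqs), names(seqs))
    if (is.null(names(seqChar)))
        stop("sequences must be named by protein id")
    rows <- lapply(seqChar, proteinDescriptor, ...)
    m <- do.call(rbind, rows)
    rownames(m) <- names(seqChar)
    featureMatrix(m)
}
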