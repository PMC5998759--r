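#' @include methods.R
NULL

#' Read a protein-protein interaction network from a TSV edge list
#'
#' Reads a HIPPIE-style three-column tab-separated edge list
#' (`idA`, `idB`, `score`) and keeps the edges whose confidence score is
#' strictly greater than `minConfidence`. Duplicate edges (in either
#' orientation) keep the maximum score; self-loops are dropped. The node set
#' is the set of endpoints of the surviving edges. Confidence scores become
#' edge weights.
#'
#' HIPPIE releases ship scores on either a 0-1000 or 0-1 scale;
#' `minConfidence` is interpreted on whatever scale the file uses, so pass
#' e.g. 800 or 0.8 accordingly.
#'
#' @param path path to the TSV file. A header line is detected (non-numeric
#'   third field) and skipped.
#' @param minConfidence keep edges with `score > minConfidence` (strict).
#' @return An [InteractionNetwork-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("P1\tP2\t900", "P2\tP3\t700"), tf)
#' readPPI(tf, minConfidence = 800)
#' @export
readPPI <- function(path, minConfidence = 800) {
    stopifnot(minConfidence >= 0)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop("empty PPI file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    if (length(fields[[1]]) >= 3 &&
        is.na(suppressWarnings(as.numeric(fields[[1]][3]))))
        start <- 2L               # header row
    if (start > length(fields))
        stop("PPI file has a header but no data rows: ", path)
    from <- character(0); to <- character(0); score <- numeric(0)
    for (i in seq(start, length(fields))) {
        f <- fields[[i]]
        if (length(f) < 3)
            stop(sprintf("malformed PPI row at line %d: expected 3 fields, got %d",
                         i, length(f)))
        s <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s))
            stop(sprintf("non-numeric confidence score at line %d: '%s'",
                         i, f[3]))
        from <- c(from, f[1]); to <- c(to, f[2]); score <- c(score, s)
    }
    keep <- score > minConfidence
    interactionNetwork(from[keep], to[keep], score[keep])
}

#' Read drug-target interaction pairs from a TSV pair list
#'
#' Reads a two-column tab-separated file of (drug_id, protein_id) pairs,
#' deduplicates, and reports the induced entity counts.
#'
#' @param path path to the TSV file; a non-data header row is skipped.
#' @param quiet suppress the summary message.
#' @return A [BipartiteDTI-class].
#' @export
readDTI <- function(path, quiet = FALSE) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    if (length(fields) >= 1 && length(fields[[1]]) >= 2 &&
        tolower(fields[[1]][1]) %in% c("drug", "drug_id", "drugid"))
        start <- 2L
    if (length(fields) < start)
        stop("DTI file contains no pairs: ", path)
    bad <- which(vapply(fields[start:length(fields)], length, 1L) < 2)
    if (length(bad))
        stop(sprintf("malformed DTI row at line %d: expected 2 fields",
                     bad[1] + start - 1L))
    drug <- vapply(fields[start:length(fields)], `[`, "", 1L)
    prot <- vapply(fields[start:length(fields)], `[`, "", 2L)
    dti <- bipartiteDTI(drug, prot)
    if (!quiet)
        message(sprintf("read %d DTI pairs (%d drugs, %d proteins)",
                        nrow(pairs(dti)), length(drugIds(dti)),
                        length(proteinIds(dti))))
    dti
}

#' Build the drug-drug interaction network from shared targets
#'
#' Connects two drugs whenever they share at least one known target protein;
#' edges carry weight 1. All drugs appearing in the DTI set become nodes, so
#' drugs whose targets are unique to them remain as isolated nodes (they
#' still need a random-walk row).
#'
#' @param dti A [BipartiteDTI-class].
#' @return An [InteractionNetwork-class] over the DTI drug set.
#' @examples
#' dti <- bipartiteDTI(c("d1", "d2", "d2", "d3"),
#'                     c("p1", "p1", "p2", "p2"))
#' edges(buildDDISharedTarget(dti))   # d1-d2 and d2-d3, not d1-d3
#' @export
buildDDISharedTarget <- function(dti) {
    pt <- pairs(dti)
    if (!nrow(pt))
        stop("cannot build a DDI network from an empty DTI set")
    byTarget <- split(pt$drug, pt$protein)
    from <- character(0); to <- character(0)
    for (ds in byTarget) {
        ds <- unique(ds)
        if (length(ds) >= 2) {
            cmb <- utils::combn(sort(ds), 2)
            from <- c(from, cmb[1, ]); to <- c(to, cmb[2, ])
        }
    }
    interactionNetwork(from, to, weight = 1, nodes = sort(unique(pt$drug)))
}

#' Read a drug fingerprint table
#'
#' Reads a CSV or TSV with a header row, first column drug id, remaining
#' columns binary fingerprint bits (substructure presence/absence), as
#' exported by fingerprint software. Values are validated to be exactly 0
#' or 1.
#'
#' @param path path to the file.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (".csv" is comma, otherwise tab).
#' @return A [FeatureMatrix-class] with one row per drug.
#' @export
readFingerprints <- function(path, sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2)
        stop("fingerprint file needs a drug_id column plus bit columns")
    ids <- df[[1]]
    bits <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage <- matrix(as.numeric(bits), nrow = nrow(bits),
                                       dimnames = dimnames(bits)))
    bad <- which(is.na(storage) | !(storage %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-binary fingerprint value at row %d (drug '%s'), column '%s': '%s'",
                     bad[1, 1], ids[bad[1, 1]],
                     colnames(bits)[bad[1, 2]], bits[bad[1, 1], bad[1, 2]]))
    rownames(storage) <- ids
    if (any(rowSums(storage) == 0))
        warning(sprintf("%d drug(s) have an all-zero fingerprint",
                        sum(rowSums(storage) == 0)))
    featureMatrix(storage)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`; record descriptions
#' are truncated at the first whitespace to give clean protein ids.
#'
#' @param path FASTA file (multi-record, wrapped lines supported).
#' @return A `Biostrings::AAStringSet` named by protein id.
#' @export
readSequences <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
}

#' Write an InteractionNetwork as a TSV edge list
#'
#' Writes `from<TAB>to<TAB>weight` rows (no header), the same dialect
#' [readPPI()] consumes, so write/read round-trips edges and weights.
#' Isolated nodes have no edges and are not representable in an edge list;
#' they are listed in an optional sidecar.
#'
#' @param net An [InteractionNetwork-class].
#' @param path output file.
#' @param nodesPath optional file to receive one node id per line (keeps
#'   isolated nodes recoverable).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, nodesPath = NULL) {
    et <- edges(net)
    writeLines(sprintf("%s\t%s\t%s", et$from, et$to,
                       format(et$weight, digits = 15, trim = TRUE,
                              scientific = FALSE)), path)
    if (!is.null(nodesPath))
        writeLines(nodeIds(net), nodesPath)
    invisible(path)
}

#' Write DTI pairs as a TSV pair list
#'
#' @param dti A [BipartiteDTI-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDTI <- function(dti, path) {
    pt <- pairs(dti)
    writeLines(c("drug\tprotein", sprintf("%s\t%s", pt$drug, pt$protein)),
               path)
    invisible(path)
}
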