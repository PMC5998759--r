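#' @include net-io.R dti-model.R
NULL

#' Generate a synthetic benchmark world
#'
#' Builds a self-consistent synthetic input set with the structure the
#' weighting method exploits: a modular interactome in which drugs acting in
#' the same module share targets, are DDI-adjacent, and carry correlated
#' fingerprints.
#'
#' \itemize{
#'   \item PPI: stochastic block model over `nModules` modules of
#'     `proteinsPerModule` proteins, edge probability `pIn` within and
#'     `pOut` across modules, with confidence scores drawn uniformly in
#'     `confRange` as edge weights (emulating a high-confidence filtered
#'     export).
#'   \item DTI: each drug belongs to one module and targets that module's
#'     anchor protein plus `targetsPerDrug - 1` random module proteins; one
#'     further within-module target per drug is held out as the test
#'     positive set (same generative rule, disjoint from training).
#'   \item DDI: exactly `buildDDISharedTarget()` of the training DTIs; the
#'     shared anchor makes each module's drugs a clique.
#'   \item Fingerprints: each module has a random template of
#'     `round(fpBits * fpDensity)` on-bits; a drug's fingerprint is the
#'     template with each bit flipped independently with probability
#'     `fpNoise`.
#'   \item Sequences: i.i.d. uniform over the 20-letter alphabet, lengths
#'     uniform in `seqLenRange` (kept above the autocorrelation maximum
#'     lag).
#' }
#'
#' @param nModules number of modules (default 4).
#' @param proteinsPerModule proteins per module (default 25).
#' @param drugsPerModule drugs per module (default 5).
#' @param pIn,pOut within-/between-module PPI edge probabilities
#'   (default 0.3 / 0.01; `pIn > pOut` required).
#' @param targetsPerDrug training targets per drug (default 3).
#' @param seqLenRange sequence length range (default c(80, 160)).
#' @param fpBits fingerprint length (default 1024).
#' @param fpDensity expected fraction of on-bits (default 0.1).
#' @param fpNoise per-bit flip probability off the module template
#'   (default 0.1).
#' @param confRange PPI confidence score range (default c(0.7, 1.0)).
#' @param rngSeed integer seed; the whole world is reproducible from it.
#' @return A [SyntheticWorld-class].
#' @export
generateWorld <- function(nModules = 4, proteinsPerModule = 25,
                          drugsPerModule = 5, pIn = 0.3, pOut = 0.01,
                          targetsPerDrug = 3, seqLenRange = c(80, 160),
                          fpBits = 1024, fpDensity = 0.1, fpNoise = 0.1,
                          confRange = c(0.7, 1.0), rngSeed = 1) {
    if (pIn <= pOut) stop("pIn must exceed pOut")
    if (fpBits < 1) stop("fpBits must be >= 1")
    if (targetsPerDrug + 1 > proteinsPerModule)
        stop("proteinsPerModule must exceed targetsPerDrug + 1")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(rngSeed)

    nProt <- nModules * proteinsPerModule
    nDrug <- nModules * drugsPerModule
    protIds <- sprintf("P%03d", seq_len(nProt))
    drugIdsV <- sprintf("D%03d", seq_len(nDrug))
    protModule <- rep(seq_len(nModules), each = proteinsPerModule)
    drugModule <- rep(seq_len(nModules), each = drugsPerModule)

    ## PPI: stochastic block model + uniform confidence scores
    pref <- matrix(pOut, nModules, nModules); diag(pref) <- pIn
    g <- igraph::sample_sbm(nProt, pref.matrix = pref,
                            block.sizes = rep(proteinsPerModule, nModules))
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi <- interactionNetwork(protIds[el[, 1]], protIds[el[, 2]],
                              weight = stats::runif(nrow(el), confRange[1],
                                                    confRange[2]),
                              nodes = protIds)

    ## DTI: anchor target (first protein of the module) + random module
    ## proteins; one extra held-out target per drug
    trainDrug <- character(0); trainProt <- character(0)
    testDrug <- character(0); testProt <- character(0)
    for (d in seq_len(nDrug)) {
        m <- drugModule[d]
        modProts <- which(protModule == m)
        anchor <- modProts[1]
        others <- sample(setdiff(modProts, anchor), targetsPerDrug)
        train <- c(anchor, others[seq_len(targetsPerDrug - 1)])
        heldOut <- others[targetsPerDrug]
        trainDrug <- c(trainDrug, rep(drugIdsV[d], length(train)))
        trainProt <- c(trainProt, protIds[train])
        testDrug <- c(testDrug, drugIdsV[d])
        testProt <- c(testProt, protIds[heldOut])
    }
    dti <- bipartiteDTI(trainDrug, trainProt)
    testDti <- bipartiteDTI(testDrug, testProt)
    ddi <- buildDDISharedTarget(dti)

    ## fingerprints: module template with per-bit noise
    nOn <- max(1L, round(fpBits * fpDensity))
    templates <- vapply(seq_len(nModules), function(m) {
        tpl <- numeric(fpBits); tpl[sample.int(fpBits, nOn)] <- 1; tpl
    }, numeric(fpBits))
    fp <- t(vapply(seq_len(nDrug), function(d) {
        tpl <- templates[, drugModule[d]]
        flip <- stats::rbinom(fpBits, 1, fpNoise)
        abs(tpl - flip)
    }, numeric(fpBits)))
    dimnames(fp) <- list(drugIdsV, sprintf("fp%04d", seq_len(fpBits)))

    ## sequences: i.i.d. uniform residues
    lens <- sample(seq(seqLenRange[1], seqLenRange[2]), nProt, replace = TRUE)
    seqs <- vapply(lens, function(L)
        paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- protIds

    new("SyntheticWorld", ppi = ppi, ddi = ddi, dti = dti, testDti = testDti,
        sequences = sequences, fingerprints = featureMatrix(fp),
        moduleOf = stats::setNames(c(protModule, drugModule),
                                   c(protIds, drugIdsV)),
        params = list(nModules = nModules,
                      proteinsPerModule = proteinsPerModule,
                      drugsPerModule = drugsPerModule, pIn = pIn, pOut = pOut,
                      targetsPerDrug = targetsPerDrug,
                      seqLenRange = seqLenRange, fpBits = fpBits,
                      fpDensity = fpDensity, fpNoise = fpNoise,
                      confRange = confRange, rngSeed = rngSeed))
}

#' Write a synthetic world in the pipeline's input formats
#'
#' Emits exactly the files the readers consume -- `ppi.tsv` and `ddi.tsv`
#' (edge lists), `dti.tsv` and `dti_test.tsv` (pair lists),
#' `fingerprints.csv` (header + binary bits) and `sequences.fasta`
#' (60-column wrapped) -- so a written world round-trips losslessly through
#' [readPPI()], [readDTI()], [readFingerprints()] and [readSequences()].
#'
#' @param world A [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeWorld <- function(world, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(ppi = file.path(dir, "ppi.tsv"),
               ddi = file.path(dir, "ddi.tsv"),
               dti = file.path(dir, "dti.tsv"),
               dtiTest = file.path(dir, "dti_test.tsv"),
               fingerprints = file.path(dir, "fingerprints.csv"),
               sequences = file.path(dir, "sequences.fasta"))
    writeNetwork(world@ppi, paths["ppi"],
                 nodesPath = file.path(dir, "ppi_nodes.txt"))
    writeNetwork(world@ddi, paths["ddi"],
                 nodesPath = file.path(dir, "ddi_nodes.txt"))
    writeDTI(world@dti, paths["dti"])
    writeDTI(world@testDti, paths["dtiTest"])
    fp <- featureValues(world@fingerprints)
    df <- data.frame(drug_id = rownames(fp), fp, check.names = FALSE)
    utils::write.csv(df, paths["fingerprints"], row.names = FALSE,
                     quote = FALSE)
    Biostrings::writeXStringSet(world@sequences, paths["sequences"],
                                width = 60)
    invisible(paths)
}
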