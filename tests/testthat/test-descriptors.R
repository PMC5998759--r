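test_that("amino acid composition is a frequency vector in fixed order", {
    v <- aac("AAAA")
    expect_equal(unname(v[1]), 1)
    expect_equal(sum(v), 1)
    v2 <- aac("ACDC")
    expect_equal(unname(v2[c("AAC.A", "AAC.C", "AAC.D")]),
                 c(0.25, 0.5, 0.25))
    expect_error(aac(""), "empty")
})

test_that("dipeptide composition counts overlapping ordered pairs", {
    v <- dpc("ACAC")
    expect_equal(unname(v["DPC.AC"]), 2 / 3)
    expect_equal(unname(v["DPC.CA"]), 1 / 3)
    expect_equal(sum(v), 1)
    expect_equal(unname(dpc("AA")["DPC.AA"]), 1)
    expect_error(dpc("A"), "length >= 2")
})

test_that("composition blocks normalize on many random sequences", {
    set.seed(42)
    for (i in 1:1000) {
        s <- randomSequence(sample(10:60, 1))
        expect_equal(sum(aac(s)), 1, tolerance = 1e-9)
        expect_equal(sum(dpc(s)), 1, tolerance = 1e-9)
    }
})

test_that("property scales standardize to mean 0, sd 1 over 20 residues", {
    m <- defaultPropertyScales()
    expect_equal(dim(m), c(8L, 20L))
    expect_equal(unname(rowMeans(m)), rep(0, 8), tolerance = 1e-9)
    expect_equal(unname(apply(m, 1, function(v) sqrt(mean(v^2)))),
                 rep(1, 8), tolerance = 1e-9)
})

test_that("autocorrelation handles degenerate homopolymers", {
    scl <- defaultPropertyScales()[1, ]
    homo <- strrep("A", 40)
    expect_equal(autocorrelation(homo, scl, 5, "moran"), rep(0, 5))
    expect_equal(autocorrelation(homo, scl, 5, "geary"), rep(0, 5))
    ## normalized Moreau-Broto of a homopolymer is P_A^2 at every lag
    expect_equal(autocorrelation(homo, scl, 5, "moreau-broto"),
                 rep(unname(scl["A"])^2, 5))
})

test_that("autocorrelation matches direct summation of the formulas", {
    set.seed(5)
    scl <- defaultPropertyScales()[3, ]
    for (rep in 1:10) {
        s <- randomSequence(sample(40:80, 1))
        for (kind in c("moreau-broto", "moran", "geary")) {
            got <- autocorrelation(s, scl, 6, kind)
            want <- vapply(1:6, function(d)
                referenceAutocorrelation(s, scl, d, kind), 0)
            expect_equal(got, want, tolerance = 1e-12)
        }
    }
})

test_that("a period-2 sequence has higher Moran autocorrelation at lag 2", {
    scl <- defaultPropertyScales()[1, ]
    s <- paste(rep(c("A", "C"), 25), collapse = "")
    ac <- autocorrelation(s, scl, 2, "moran")
    expect_gt(ac[2], ac[1])
    expect_equal(ac[1],
                 referenceAutocorrelation(s, scl, 1, "moran"),
                 tolerance = 1e-12)
    expect_equal(ac[2],
                 referenceAutocorrelation(s, scl, 2, "moran"),
                 tolerance = 1e-12)
})

test_that("sequences exceeding maxlag are required", {
    scl <- defaultPropertyScales()[1, ]
    expect_error(autocorrelation("ACDEF", scl, 10), "maxlag")
})

test_that("CTD matches a hand-traced example", {
    ## charge attribute: K is group 1 (positive), A is group 2 (neutral),
    ## so KKKKKAAAAA has group pattern 1111122222
    v <- ctd("KKKKKAAAAA")
    expect_equal(unname(v["CTDT.charge.g1g2"]), 1 / 9)
    expect_equal(unname(v["CTDD.charge.g2.first"]), 60)
    expect_equal(unname(v["CTDC.charge.g1"]), 0.5)
    expect_equal(unname(v["CTDC.charge.g2"]), 0.5)
    expect_equal(unname(v["CTDD.charge.g1.first"]), 10)
    expect_equal(unname(v["CTDD.charge.g1.last"]), 50)
    ## group 3 (D/E) absent: all distribution entries 0
    expect_equal(unname(v[sprintf("CTDD.charge.g3.%s",
                                  c("first", "p25", "p50", "p75", "last"))]),
                 rep(0, 5))
})

test_that("CTD composition sums to 1 per attribute", {
    set.seed(9)
    for (i in 1:50) {
        v <- ctd(randomSequence(sample(20:80, 1)))
        for (attr in names(defaultCTDGroups())) {
            comp <- v[sprintf("CTDC.%s.g%d", attr, 1:3)]
            expect_equal(sum(comp), 1, tolerance = 1e-9)
        }
    }
})

test_that("a sequence entirely in one group degenerates correctly", {
    ## "KRKRKR": all residues in charge group 1
    v <- ctd("KRKRKR")
    expect_equal(unname(v["CTDC.charge.g1"]), 1)
    expect_equal(unname(v[sprintf("CTDT.charge.%s",
                                  c("g1g2", "g1g3", "g2g3"))]), rep(0, 3))
    expect_equal(unname(v[sprintf("CTDD.charge.g2.%s",
                                  c("first", "p25", "p50", "p75", "last"))]),
                 rep(0, 5))
})

test_that("the full descriptor has 1287 dimensions in fixed block order", {
    set.seed(2)
    s <- randomSequence(60)
    d <- proteinDescriptor(s)
    expect_length(d, 1287)
    bl <- descriptorBlockLengths()
    expect_equal(unname(bl), c(20L, 400L, 240L, 240L, 240L, 21L, 21L, 105L))
    expect_equal(sum(bl), 1287L)
    ## prefixes appear in block order at the right offsets
    offsets <- cumsum(c(0, bl[-length(bl)])) + 1
    expect_match(names(d)[offsets[1]], "^AAC\\.")
    expect_match(names(d)[offsets[2]], "^DPC\\.")
    expect_match(names(d)[offsets[3]], "^NMB\\.")
    expect_match(names(d)[offsets[4]], "^MORAN\\.")
    expect_match(names(d)[offsets[5]], "^GEARY\\.")
    expect_match(names(d)[offsets[6]], "^CTDC\\.")
    expect_match(names(d)[offsets[7]], "^CTDT\\.")
    expect_match(names(d)[offsets[8]], "^CTDD\\.")
    ## pure function of the sequence
    expect_identical(d, proteinDescriptor(s))
})

test_that("non-canonical residues are removed with a warning", {
    expect_warning(s <- sanitizeSequence("ACDXUZACDEFGHIKLMNPQRSTVWY"),
                   "non-canonical")
    expect_false(grepl("[XUZ]", s))
    expect_error(sanitizeSequence("ACDX", strict = TRUE), "non-canonical")
})

test_that("descriptor matrices align rows with sequence names", {
    set.seed(8)
    seqs <- setNames(vapply(1:3, function(i) randomSequence(50), ""),
                     c("pA", "pB", "pC"))
    fm <- proteinDescriptorMatrix(seqs)
    expect_equal(entityIds(fm), c("pA", "pB", "pC"))
    expect_equal(ncol(featureValues(fm)), 1287)
    expect_equal(featureValues(fm)["pB", ],
                 proteinDescriptor(seqs["pB"]))
})
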