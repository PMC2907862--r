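test_that("single-cell and gapless alignments score as expected", {
    s62 <- SCHEMES[[1]]
    expect_identical(swScore("A", "A", s62), 4L)
    expect_identical(swScore("AAAA", "AAAA", s62), 16L)
    # all pairwise substitution scores <= 0: H stays clamped at zero
    expect_identical(swScore("WWWW", "PPPP", s62), 0L)
})

test_that("the classic textbook instance scores 28", {
    s50 <- scoringScheme(B50, gapPenalty(0, 8))
    expect_identical(swScore("HEAGAWGHEE", "PAWHEAE", s50), 28L)
})

test_that("full tables satisfy the boundary and best-score invariants", {
    set.seed(71)
    for (k in 1:15) {
        p <- samplePair(1L, 60L); sch <- sampleScheme()
        f <- swFull(p$q, p$s, sch)
        expect_true(all(f$H[1L, ] == 0L))
        expect_true(all(f$H[, 1L] == 0L))
        expect_true(all(f$E[, 1L] == 0L))
        expect_true(all(f$F[1L, ] == 0L))
        expect_true(all(f$H >= 0L))
        expect_identical(f$best, max(f$H))
        expect_identical(f$best, swScore(p$q, p$s, sch))
    }
})

test_that("scalar engine matches an independent anti-diagonal evaluation", {
    # recomputing in minor-diagonal order must give identical tables to the
    # row-major compiled engine (the cell dependencies only reach the two
    # previous diagonals)
    set.seed(81)
    for (k in 1:8) {
        p <- samplePair(1L, 40L); sch <- sampleScheme()
        f <- swFull(p$q, p$s, sch)
        g <- swAntiDiagonalR(p$q, p$s, sch)
        expect_identical(unname(f$H), g$H)
        expect_identical(unname(f$E[, -1L, drop = FALSE]),
                         g$E[, -1L, drop = FALSE])
        expect_identical(unname(f$F[-1L, , drop = FALSE]),
                         g$F[-1L, , drop = FALSE])
    }
})

test_that("scalar engine matches Biostrings local alignment scores", {
    ref62 <- get(data("BLOSUM62", package = "Biostrings",
                      envir = environment()))
    set.seed(91)
    for (k in 1:12) {
        q <- randomProtein(sample(5:80, 1L))
        s <- mutateHomolog(q, 0.3, 0.05)
        sch <- scoringScheme(B62, sprintf("%d-%dk", sample(5:20, 1L),
                                          sample(1:4, 1L)))
        mine <- swScore(q, s, sch)
        ref <- Biostrings::pairwiseAlignment(
            q, s, type = "local", substitutionMatrix = ref62,
            gapOpening = gapOpen(sch), gapExtension = gapExtend(sch),
            scoreOnly = TRUE)
        expect_identical(as.integer(ref), mine)
    }
})

test_that("score is symmetric and monotone under extension", {
    set.seed(111)
    for (k in 1:10) {
        p <- samplePair(1L, 60L); sch <- sampleScheme()
        expect_identical(swScore(p$q, p$s, sch), swScore(p$s, p$q, sch))
        # appending residues never decreases a local score
        ext <- paste0(p$q, randomProtein(10L))
        expect_gte(swScore(ext, p$s, sch), swScore(p$q, p$s, sch))
        # extending with dummy residues changes nothing
        qd <- c(encodeSequence(p$q, sch), rep(dummyCode(sch), 7L))
        expect_identical(swScore(qd, p$s, sch), swScore(p$q, p$s, sch))
    }
})

test_that("H tables transpose under query/subject swap", {
    set.seed(121)
    p <- samplePair(5L, 40L); sch <- sampleScheme()
    a <- swFull(p$q, p$s, sch)
    b <- swFull(p$s, p$q, sch)
    expect_identical(unname(a$H), unname(t(b$H)))
})

test_that("degenerate inputs are rejected", {
    expect_error(swScore("", "AA", SCHEMES[[1]]), "non-empty")
    expect_error(swScore("AA", "", SCHEMES[[1]]), "non-empty")
})
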