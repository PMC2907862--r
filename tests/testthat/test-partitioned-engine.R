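test_that("partition plans slice, pad and validate", {
    q <- randomProtein(600L, seed = 171)
    plan <- partitionQuery(q, B62, pl = 256L, vl = 16L)
    expect_identical(length(plan@partitions), 3L)
    expect_true(all(lengths(plan@partitions) == 256L))
    # last partition carries 3*256 - 600 = 168 dummy residues
    expect_identical(sum(unlist(plan@partitions) == dummyCode(B62)), 168L)
    # concatenating and trimming reproduces the query
    codes <- unlist(plan@partitions)
    expect_identical(codes[seq_len(600L)], encodeSequence(q, B62))
    expect_true(all(vapply(plan@profiles, segmentCountOf, 1L) == 16L))
    expect_error(partitionQuery(q, B62, pl = 10L, vl = 4L), "multiple")
})

test_that("boundary carry follows max(H - open - extend, F - extend)", {
    g <- gapPenalty(10L, 2L)
    expect_identical(carryBoundary(20L, 5L, g), 8L)
    # stale-F case: the H path dominates
    expect_identical(carryBoundary(20L, 0L, g), 8L)
    # zero boundary values: max(0 - 12, 0 - 2) = -2, a negative carry that
    # can never raise an H
    expect_identical(carryBoundary(0L, 0L, g), -2L)
    # vectorized over columns
    expect_identical(carryBoundary(c(20L, 0L), c(5L, 0L), g), c(8L, -2L))
})

test_that("partitioned scores equal the scalar oracle on random pairs", {
    set.seed(181)
    for (k in 1:50) {
        p <- samplePair(1L, 100L); sch <- sampleScheme()
        vl <- sample(c(2L, 4L, 8L, 16L), 1L)
        pl <- vl * sample(c(1L, 2L, 4L), 1L)
        expect_identical(partitionedSwScore(p$q, p$s, sch, pl = pl, vl = vl),
                         swScore(p$q, p$s, sch))
    }
})

test_that("a query shorter than PL reduces to the striped engine", {
    set.seed(191)
    p <- samplePair(10L, 60L); sch <- sampleScheme()
    expect_identical(partitionedSwScore(p$q, p$s, sch, pl = 256L, vl = 16L),
                     stripedSwScore(p$q, p$s, sch, vl = 16L))
})

test_that("scores are invariant to the partitioning", {
    set.seed(201)
    p <- samplePair(60L, 120L); sch <- sampleScheme()
    ref <- swScore(p$q, p$s, sch)
    for (vl in c(2L, 4L, 8L)) {
        for (mult in c(1L, 2L, 4L, 8L)) {
            expect_identical(partitionedSwScore(p$q, p$s, sch,
                                                pl = vl * mult, vl = vl),
                             ref)
        }
    }
})

test_that("carried boundary F values are exact in both lazy-F cases", {
    set.seed(211)
    nFull <- 0L; nEarly <- 0L
    for (k in 1:20) {
        p <- samplePair(20L, 80L); sch <- sampleScheme()
        vl <- sample(c(2L, 4L, 8L), 1L)
        pl <- vl * sample(c(1L, 2L), 1L)
        tr <- partitionedAlignmentTrace(p$q, p$s, sch, pl = pl, vl = vl)
        f <- swFull(p$q, p$s, sch)
        for (b in seq_along(tr$boundaries)) {
            bd <- tr$boundaries[[b]]
            expect_identical(bd$Hlast, unname(f$H[b * pl + 1L, -1L]))
            expect_identical(bd$Fnext, unname(f$F[b * pl + 2L, -1L]))
            nFull <- nFull + sum(bd$lazyFull)
            nEarly <- nEarly + sum(!bd$lazyFull)
        }
    }
    # the instrumented sample must exercise both theorem cases
    expect_gt(nFull, 0L)
    expect_gt(nEarly, 0L)
})

test_that("E values at partition-first rows do not depend on PL", {
    # E carries no cross-row state, so partitioning must leave it untouched
    set.seed(221)
    p <- samplePair(40L, 80L); sch <- sampleScheme()
    f <- swFull(p$q, p$s, sch)
    for (vl in c(2L, 4L)) for (mult in c(1L, 3L)) {
        pl <- vl * mult
        tr <- partitionedAlignmentTrace(p$q, p$s, sch, pl = pl, vl = vl)
        for (pp in seq_len(tr$nPartitions)) {
            rowFirst <- (pp - 1L) * pl + 1L
            if (rowFirst <= nchar(p$q)) {
                expect_identical(tr$firstRowE[pp, ],
                                 unname(f$E[rowFirst + 1L, -1L]))
            }
        }
    }
})

test_that("dummy padding in the last partition never changes the score", {
    set.seed(231)
    for (k in 1:8) {
        sch <- sampleScheme()
        vl <- 4L; pl <- 16L
        l <- sample(17:47, 1L)   # deliberately not a multiple of pl
        p <- list(q = randomProtein(l), s = randomProtein(40L))
        expect_identical(partitionedSwScore(p$q, p$s, sch, pl = pl, vl = vl),
                         swScore(p$q, p$s, sch))
    }
})
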