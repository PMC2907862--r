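test_that("segment count is the ceiling of l / VL", {
    expect_identical(segmentCount(16, 4), 4L)
    expect_identical(segmentCount(17, 4), 5L)
    expect_identical(segmentCount(5, 8), 1L)
    expect_error(segmentCount(0, 4), "positive")
    expect_error(segmentCount(4, 0), "positive")
})

test_that("sequential profile equals direct matrix lookup", {
    p <- buildSequentialProfile("AC", B62)
    syms <- alphabetSymbols(B62)
    expect_identical(unname(profileValues(p)[match("A", syms), ]),
                     c(4L, 0L))
    set.seed(21)
    for (k in 1:5) {
        q <- randomProtein(sample(1:80, 1L))
        codes <- encodeSequence(q, B62)
        p <- buildSequentialProfile(codes, B62)
        expect_identical(ncol(profileValues(p)), length(codes))
        expect_identical(unname(profileValues(p)),
                         unname(scoreTable(B62)[, codes, drop = FALSE]))
    }
    expect_error(buildSequentialProfile("", B62), "non-empty")
})

test_that("padded positions score zero against every residue", {
    p <- buildSequentialProfile("ACD", B62, padTo = 4L)
    expect_identical(ncol(profileValues(p)), 4L)
    expect_true(all(profileValues(p)[, 4L] == 0L))
    sp <- buildStripedProfile("ACDEF", B62, vl = 4L)   # T = 2, 3 padded
    v <- profileValues(sp)
    tt <- segmentCountOf(sp)
    for (v1 in 1:4) for (s1 in 1:2) {
        qpos <- (v1 - 1L) * tt + s1
        if (qpos > 5L) expect_true(all(v[v1, s1, ] == 0L))
    }
})

test_that("striped layout interleaves query positions as specified", {
    # l = 8, VL = 4 (T = 2): reading the striped positions segment by
    # segment, lane by lane, visits query indices 0,2,4,6,1,3,5,7 (0-based)
    q <- "ARNDCQEG"
    sp <- buildStripedProfile(q, B62, vl = 4L)
    codes <- encodeSequence(q, B62)
    sq <- scoreTable(B62)[, codes]
    v <- profileValues(sp)
    tt <- segmentCountOf(sp)
    expect_identical(tt, 2L)
    for (r in seq_len(dim(v)[3L])) {
        bySegment <- c(v[, 1L, r], v[, 2L, r])   # segment-major order
        expect_identical(bySegment,
                         unname(sq[r, c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)]))
    }
})

test_that("VL = 1 striped profile equals the sequential profile", {
    set.seed(31)
    q <- randomProtein(23)
    sp <- buildStripedProfile(q, B62, vl = 1L)
    sq <- buildSequentialProfile(q, B62)
    expect_identical(matrix(profileValues(sp), nrow = dim(profileValues(sp))[3L],
                            byrow = TRUE),
                     unname(profileValues(sq)))
})

test_that("de-striping reconstructs the sequential profile", {
    set.seed(41)
    for (k in 1:20) {
        l <- sample(1:120, 1L); vl <- sample(1:40, 1L)
        q <- randomProtein(l)
        sp <- buildStripedProfile(q, B62, vl = vl)
        sq <- buildSequentialProfile(q, B62)
        expect_identical(unname(profileValues(deStripe(sp))),
                         unname(profileValues(sq)))
        # permutation property: striped values = sequential values + zeros
        v <- profileValues(sp)
        for (r in sample(dim(v)[3L], 3L)) {
            striped <- sort(as.vector(v[, , r]))
            sequential <- sort(c(profileValues(sq)[r, ],
                                 rep(0L, segmentCountOf(sp) * vl - l)))
            expect_identical(striped, sequential)
        }
    }
})

test_that("de-striping a lane matrix follows v*T + s order", {
    m <- matrix(1:6, nrow = 2L, byrow = TRUE)  # VL = 2, T = 3
    expect_identical(deStripe(m), c(1L, 2L, 3L, 4L, 5L, 6L))
    m2 <- matrix(c(10L, 30L, 20L, 40L), nrow = 2L)  # lanes hold 10,20 / 30,40
    expect_identical(deStripe(m2), c(10L, 20L, 30L, 40L))
})
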