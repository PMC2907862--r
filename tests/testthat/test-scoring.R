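test_that("built-in matrices carry the published scores", {
    syms <- alphabetSymbols(B62)
    expect_true(all(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "B", "Z",
                      "X", "*") %in% syms))
    sc62 <- scoreTable(B62)
    expect_identical(sc62[match("A", syms), match("A", syms)], 4L)
    expect_identical(sc62[match("W", syms), match("W", syms)], 11L)
    sc50 <- scoreTable(B50)
    syms50 <- alphabetSymbols(B50)
    expect_identical(sc50[match("W", syms50), match("W", syms50)], 15L)

    # independent reference: the matrices shipped with Biostrings
    # (core 20x20 block; Biostrings carries a newer ambiguity-row variant)
    ref62 <- get(data("BLOSUM62", package = "Biostrings",
                      envir = environment()))
    ref50 <- get(data("BLOSUM50", package = "Biostrings",
                      envir = environment()))
    aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    mine62 <- sc62[match(aa, syms), match(aa, syms)]
    mine50 <- sc50[match(aa, syms50), match(aa, syms50)]
    expect_identical(unname(mine62), unname(ref62[aa, aa]))
    expect_identical(unname(mine50), unname(ref50[aa, aa]))
    # BLOSUM50 matches the reference on every shared letter
    shared <- intersect(syms50, colnames(ref50))
    expect_identical(unname(sc50[match(shared, syms50),
                                 match(shared, syms50)]),
                     unname(ref50[shared, shared]))
})

test_that("matrices are symmetric and the dummy code scores zero", {
    for (m in list(B62, B50)) {
        sc <- scoreTable(m)
        expect_identical(sc, t(sc))
        d <- dummyCode(m)
        expect_true(all(sc[d, ] == 0L))
        expect_true(all(sc[, d] == 0L))
        expect_false(as.character(d) %in% alphabetSymbols(m))
    }
})

test_that("matrix loading rejects bad inputs with informative errors", {
    expect_error(loadMatrix("BLOSUM99"), "unknown substitution matrix")
    bad <- tempfile(fileext = ".txt")
    writeLines(c("   A  C", "A  4 -1", "C -2  9"), bad)
    expect_error(loadMatrix(bad), "asymmetric at pair \\([AC], [AC]\\)")
    nonsq <- tempfile(fileext = ".txt")
    writeLines(c("   A  C", "A  4 -1"), nonsq)
    expect_error(loadMatrix(nonsq), "square")
})

test_that("user matrix files in NCBI layout load with comments", {
    f <- tempfile(fileext = ".txt")
    writeLines(c("# a tiny custom matrix", "   A  C  X",
                 "A  4  0  1", "C  0  9  1", "X  1  1  1"), f)
    m <- loadMatrix(f)
    expect_identical(alphabetSymbols(m), c("A", "C", "X"))
    expect_identical(scoreTable(m)[1L, 2L], 0L)
    expect_identical(scoreTable(m)[2L, 2L], 9L)
})

test_that("gap specifications parse and round-trip", {
    g <- parseGapSpec("10-2k")
    expect_identical(gapOpen(g), 10L)
    expect_identical(gapExtend(g), 2L)
    g2 <- parseGapSpec("40-3 k")
    expect_identical(c(gapOpen(g2), gapExtend(g2)), c(40L, 3L))
    g3 <- parseGapSpec("7/5")
    expect_identical(c(gapOpen(g3), gapExtend(g3)), c(7L, 5L))

    set.seed(101)
    for (k in 1:40) {
        q <- sample(0:100, 1L); r <- sample(1:20, 1L)
        g <- parseGapSpec(sprintf("%d-%dk", q, r))
        expect_identical(c(gapOpen(g), gapExtend(g)), c(q, r))
    }
})

test_that("zero or malformed gap extension is rejected", {
    expect_error(parseGapSpec("10-0k"), "extension")
    expect_error(parseGapSpec("10k"), "malformed")
    expect_error(parseGapSpec("-3-2k"), "malformed")
    expect_error(gapPenalty(10, 0), "extension")
    expect_error(gapPenalty(-1, 2), "open")
})

test_that("sequence encoding folds case, strips and maps unknowns", {
    syms <- alphabetSymbols(B62)
    expect_identical(encodeSequence("acgt", B62),
                     match(c("A", "C", "G", "T"), syms))
    expect_identical(encodeSequence("A A*", B62), match(c("A", "A"), syms))
    expect_identical(encodeSequence("A?A", B62),
                     match(c("A", "X", "A"), syms))
    expect_error(encodeSequence("A?A", B62, strict = TRUE),
                 "unknown residue")
    # encode then decode is the identity on in-alphabet strings
    set.seed(7)
    for (k in 1:10) {
        s <- randomProtein(sample(1:60, 1L))
        expect_identical(decodeSequence(encodeSequence(s, B62), B62), s)
    }
})
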