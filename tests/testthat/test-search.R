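test_that("FASTA parsing follows the standard record contract", {
    f <- tempfile(fileext = ".fasta")
    writeLines(c(">rec1 first record", "ARNDCQ", "EGHI",
                 "", ">rec2 second", "wklm*",
                 ">rec3 stops only", "***"), f)
    expect_warning(db <- readFastaDb(f), "rec3")
    expect_identical(length(db), 2L)
    expect_identical(unname(nchar(db)), c(10L, 4L))
    expect_identical(unname(db[1L]), "ARNDCQEGHI")   # lines concatenated
    expect_identical(unname(db[2L]), "WKLM")          # '*' stripped, upcased
    expect_identical(sub(" .*", "", names(db)), c("rec1", "rec2"))
    expect_error(readFastaDb(tempfile()), "not found")
})

test_that("self hit ranks first and engines agree on the ranking", {
    set.seed(241)
    q <- randomProtein(80L)
    db <- c(self = q,
            shuffled = paste(sample(strsplit(q, "")[[1]]), collapse = ""),
            random = randomProtein(80L))
    sch <- SCHEMES[[1]]
    res <- searchDatabase(q, db, sch, engine = "scalar", topk = 3L)
    h <- hits(res)
    expect_identical(h$subject_id[1L], "self")
    expect_identical(h$score[1L], swScore(q, q, sch))
    expect_false(is.unsorted(rev(h$score)))
    for (eng in c("striped", "partitioned")) {
        res2 <- searchDatabase(q, db, sch, engine = eng, vl = 8L, pl = 16L,
                               topk = 3L)
        expect_identical(hits(res2), h)
    }
})

test_that("rankings are stable, clamped and correctly counted", {
    set.seed(251)
    db <- generateDatabase(fixtureSpec(12L, "uniform", 30L, 70L, seed = 5L))
    q <- randomProtein(50L)
    sch <- SCHEMES[[4]]
    res <- searchDatabase(q, db, sch, engine = "scalar", topk = 100L)
    h <- hits(res)
    expect_identical(nrow(h), 12L)                   # topk clamped
    expect_identical(h$rank, 1:12)
    # ties keep database input order
    tied <- split(h$subject_id, h$score)
    for (grp in tied) {
        idx <- match(grp, sub(" .*", "", names(db)))
        expect_false(is.unsorted(idx))
    }
    # cell count is query length x total database residues
    expect_identical(searchMetadata(res)$cellCount,
                     50 * sum(nchar(db)))
})

test_that("engines produce identical rankings on a synthetic database", {
    set.seed(261)
    base <- randomProtein(70L)
    db <- c(generateDatabase(fixtureSpec(8L, "uniform", 40L, 90L, seed = 6L)),
            hom1 = mutateHomolog(base, 0.1, 0.02),
            hom2 = mutateHomolog(base, 0.4, 0.05))
    sch <- SCHEMES[[3]]
    ref <- searchDatabase(base, db, sch, engine = "scalar", topk = 10L)
    a <- searchDatabase(base, db, sch, engine = "striped", vl = 8L,
                        topk = 10L)
    b <- searchDatabase(base, db, sch, engine = "partitioned", vl = 4L,
                        pl = 32L, topk = 10L)
    expect_identical(hits(a), hits(ref))
    expect_identical(hits(b), hits(ref))
})

test_that("GCUPS follows its unit definition", {
    expect_identical(computeGcups(1e9, 1), 1)
    expect_identical(computeGcups(0, 1), 0)
    expect_identical(computeGcups(5e9, 2), 2.5)
    expect_identical(computeGcups(1e9, 2), computeGcups(1e9, 1) / 2)
    expect_error(computeGcups(1e9, 0), "positive")
})

test_that("search rejects invalid engine configurations", {
    db <- c(a = "ARND")
    expect_error(searchDatabase("ARND", db, SCHEMES[[1]],
                                engine = "partitioned", vl = 3L, pl = 10L),
                 "multiple")
    expect_error(searchDatabase("ARND", db, SCHEMES[[1]], engine = "bogus"),
                 "arg")
})
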