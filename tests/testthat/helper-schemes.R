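# Shared fixtures: schemes are loaded once, random instances are generated
# in code under fixed seeds.

B62 <- loadMatrix("BLOSUM62")
B50 <- loadMatrix("BLOSUM50")
SCHEMES <- list(
    scoringScheme(B62, "10-2k"),
    scoringScheme(B62, "20-2k"),
    scoringScheme(B62, "40-3k"),
    scoringScheme(B50, "10-2k"),
    scoringScheme(B50, "20-2k"),
    scoringScheme(B50, "40-3k"))

sampleScheme <- function() SCHEMES[[sample.int(length(SCHEMES), 1L)]]

samplePair <- function(minLen = 1L, maxLen = 120L) {
    list(q = randomProtein(sample.int(maxLen - minLen + 1L, 1L) + minLen - 1L),
         s = randomProtein(sample.int(maxLen - minLen + 1L, 1L) + minLen - 1L))
}

# Independent pure-R affine-gap Smith-Waterman, evaluated in minor-diagonal
# order (all cells of a minor diagonal depend only on the two previous
# diagonals).  Used as an oracle for the compiled scalar engine and as the
# evaluation-order property check.
swAntiDiagonalR <- function(q, s, scheme) {
    q <- encodeSequence(q, scheme); s <- encodeSequence(s, scheme)
    sbt <- scoreTable(scheme)
    goe <- gapOpen(scheme) + gapExtend(scheme)
    ge <- gapExtend(scheme)
    l1 <- length(q); l2 <- length(s)
    H <- matrix(0L, l1 + 1L, l2 + 1L)
    E <- matrix(0L, l1 + 1L, l2 + 1L)
    FF <- matrix(0L, l1 + 1L, l2 + 1L)
    for (d in seq.int(2L, l1 + l2)) {
        for (i in seq.int(max(1L, d - l2), min(l1, d - 1L))) {
            j <- d - i
            e <- max(H[i + 1L, j] - goe, E[i + 1L, j] - ge)
            f <- max(H[i, j + 1L] - goe, FF[i, j + 1L] - ge)
            h <- max(0L, H[i, j] + sbt[q[i], s[j]], e, f)
            E[i + 1L, j + 1L] <- e
            FF[i + 1L, j + 1L] <- f
            H[i + 1L, j + 1L] <- h
        }
    }
    list(H = H, E = E, F = FF, best = max(H))
}
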