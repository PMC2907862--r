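## Seeded synthetic protein sequence generation, so every test and demo
## runs without downloads.  One explicit seed is threaded through all
## generators; the caller's global random state is saved and restored, so
## repeated calls with the same arguments are byte-identical and nothing
## leaks between calls.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Typical residue frequencies of a large curated protein database
## (rounded to 0.1%); provided for realism, never required by the tests.
.AA_DB_FREQ <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014,
                 Q = 0.039, E = 0.067, G = 0.071, H = 0.023, I = 0.059,
                 L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
                 S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.069)

#' Residue composition tables
#'
#' @param kind \code{"uniform"} (equal frequency over the 20 standard amino
#'   acids; the default used by the generators) or \code{"database"}
#'   (typical frequencies of a large curated protein database).
#' @return Named numeric vector of frequencies summing to 1.
#' @export
aaComposition <- function(kind = c("uniform", "database")) {
    kind <- match.arg(kind)
    if (kind == "uniform")
        stats::setNames(rep(1 / 20, 20L), .AA20)
    else
        .AA_DB_FREQ / sum(.AA_DB_FREQ)
}

.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.checkComposition <- function(composition) {
    if (is.null(composition)) composition <- aaComposition("uniform")
    stopifnot(is.numeric(composition), !is.null(names(composition)),
              all(composition >= 0), sum(composition) > 0)
    composition / sum(composition)
}

#' Random protein sequence
#'
#' Draws residues independently from a composition table.  Deterministic
#' for a given (length, seed, composition); the caller's random state is
#' untouched.
#'
#' @param length Sequence length (>= 0).
#' @param seed Integer seed; \code{NULL} uses (and advances) the current
#'   random state.
#' @param composition Named residue-frequency vector; default uniform over
#'   the 20 standard amino acids.
#' @return Character residue string.
#' @examples
#' randomProtein(10, seed = 1)
#' @export
randomProtein <- function(length, seed = NULL, composition = NULL) {
    length <- as.integer(length)
    if (is.na(length) || length < 0L)
        stop("length must be non-negative", call. = FALSE)
    if (length == 0L) return("")
    composition <- .checkComposition(composition)
    .withSeed(seed, paste(sample(names(composition), length, replace = TRUE,
                                 prob = composition), collapse = ""))
}

#' Mutated homolog of a sequence
#'
#' Derives a related sequence: each position is independently substituted
#' (by a residue drawn from the composition, forced to differ) with
#' probability \code{substitutionRate}; insertion/deletion events occur at
#' each position with probability \code{indelRate}, with geometric lengths
#' (mean 2).  Deterministic given the seed.  Homologs retain diagonal
#' signal, so searches against them score above unrelated sequences.
#'
#' @param sequence Residue string.
#' @param substitutionRate,indelRate Per-position event probabilities in
#'   [0, 1].
#' @param seed Integer seed; \code{NULL} uses the current random state.
#' @param composition Residue-frequency vector for replacement/inserted
#'   residues; default uniform.
#' @return Character residue string.
#' @examples
#' s <- randomProtein(50, seed = 1)
#' mutateHomolog(s, 0.1, 0.01, seed = 2)
#' @export
mutateHomolog <- function(sequence, substitutionRate = 0.1,
                          indelRate = 0.01, seed = NULL,
                          composition = NULL) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (substitutionRate < 0 || substitutionRate > 1 ||
        indelRate < 0 || indelRate > 1)
        stop("mutation rates must lie in [0, 1]", call. = FALSE)
    composition <- .checkComposition(composition)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (n == 0L) return("")
    .withSeed(seed, {
        hit <- runif(n) < substitutionRate
        if (any(hit)) {
            repl <- vapply(chars[hit], function(ch) {
                w <- composition
                w[names(w) == ch] <- 0
                sample(names(w), 1L, prob = w)
            }, "", USE.NAMES = FALSE)
            chars[hit] <- repl
        }
        if (indelRate > 0) {
            out <- character(0L)
            i <- 1L
            while (i <= length(chars)) {
                if (runif(1L) < indelRate) {
                    len <- rgeom(1L, 0.5) + 1L
                    if (runif(1L) < 0.5) {        # insertion before i
                        ins <- sample(names(composition), len,
                                      replace = TRUE, prob = composition)
                        out <- c(out, ins, chars[i])
                        i <- i + 1L
                    } else {                      # deletion of len residues
                        i <- i + len
                    }
                } else {
                    out <- c(out, chars[i])
                    i <- i + 1L
                }
            }
            chars <- out
        }
        paste(chars, collapse = "")
    })
}

#' Specify a synthetic database
#'
#' @param nRecords Number of records.
#' @param lengthLaw \code{"fixed"}, \code{"uniform"} or
#'   \code{"logUniform"}.
#' @param lengthA Fixed length, or lower length bound.
#' @param lengthB Upper length bound (ignored for \code{"fixed"}).
#' @param seed Integer seed.
#' @param composition Residue-frequency vector; default uniform.
#' @return A \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nRecords, lengthLaw = c("fixed", "uniform",
                                                "logUniform"),
                        lengthA, lengthB = lengthA, seed = 1L,
                        composition = NULL) {
    new("FixtureSpec", nRecords = as.integer(nRecords),
        lengthLaw = match.arg(lengthLaw), lengthA = as.integer(lengthA),
        lengthB = as.integer(lengthB), seed = as.integer(seed),
        composition = .checkComposition(composition))
}

#' Generate a synthetic protein database
#'
#' Draws \code{nRecords} sequences with lengths from the specification's
#' length law and residues from its composition.  Record headers are
#' \code{"synth_<i> len=<L> seed=<seed>"}.  Re-running with the same
#' specification reproduces the database (and any written FASTA file)
#' byte for byte.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @param path Optional FASTA output path.
#' @return A named character vector of sequences (invisibly when
#'   \code{path} is given).
#' @examples
#' db <- generateDatabase(fixtureSpec(3, "fixed", 50, seed = 1))
#' nchar(db)
#' @export
generateDatabase <- function(spec, path = NULL) {
    stopifnot(is(spec, "FixtureSpec"))
    seqs <- .withSeed(spec@seed, {
        lens <- switch(spec@lengthLaw,
            fixed = rep.int(spec@lengthA, spec@nRecords),
            uniform = as.integer(floor(runif(spec@nRecords, spec@lengthA,
                                             spec@lengthB + 1))),
            logUniform = as.integer(floor(exp(runif(spec@nRecords,
                                                    log(spec@lengthA),
                                                    log(spec@lengthB + 1))))))
        lens <- pmin(lens, max(spec@lengthA, spec@lengthB))
        vapply(lens, function(L) {
            if (L == 0L) "" else
            paste(sample(names(spec@composition), L, replace = TRUE,
                         prob = spec@composition), collapse = "")
        }, "")
    })
    names(seqs) <- sprintf("synth_%d len=%d seed=%d", seq_along(seqs),
                           nchar(seqs), spec@seed)
    if (!is.null(path)) {
        Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                                    filepath = path, width = 60L)
        return(invisible(seqs))
    }
    seqs
}
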