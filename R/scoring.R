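## Alphabet encoding, substitution matrices and gap-penalty parameterization
## shared by all alignment engines.

.BUILTIN_MATRICES <- c("BLOSUM62", "BLOSUM50")

Alphabet <- function(symbols) {
    new("Alphabet", symbols = toupper(as.character(symbols)))
}

#' @describeIn alphabet-accessors Symbols of an alphabet.
#' @export
setMethod("alphabetSymbols", "Alphabet", function(x) x@symbols)

#' Alphabet and dummy-code accessors
#'
#' @param x An \linkS4class{Alphabet}, \linkS4class{SubstitutionMatrix} or
#'   \linkS4class{ScoringScheme}.
#' @return \code{alphabet} returns the \linkS4class{Alphabet};
#'   \code{alphabetSymbols} its character symbols; \code{dummyCode} the
#'   integer code reserved for the zero-scoring padding residue.
#' @name alphabet-accessors
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' alphabetSymbols(m)
#' dummyCode(m)
NULL

#' @describeIn alphabet-accessors Dummy (padding) code of an alphabet: one
#'   past the last symbol code.
#' @export
setMethod("dummyCode", "Alphabet", function(x) length(x@symbols) + 1L)

#' @describeIn alphabet-accessors Alphabet of a substitution matrix.
#' @export
setMethod("alphabet", "SubstitutionMatrix", function(x) x@alphabet)

#' @describeIn alphabet-accessors Symbols of a matrix's alphabet.
#' @export
setMethod("alphabetSymbols", "SubstitutionMatrix",
          function(x) x@alphabet@symbols)

#' @describeIn alphabet-accessors Dummy code of a matrix's alphabet.
#' @export
setMethod("dummyCode", "SubstitutionMatrix",
          function(x) dummyCode(x@alphabet))

#' @describeIn alphabet-accessors Alphabet of a scoring scheme.
#' @export
setMethod("alphabet", "ScoringScheme", function(x) x@matrix@alphabet)

#' @describeIn alphabet-accessors Dummy code of a scheme's alphabet.
#' @export
setMethod("dummyCode", "ScoringScheme", function(x) dummyCode(x@matrix))

#' Scoring-scheme accessors
#'
#' @param x A \linkS4class{SubstitutionMatrix}, \linkS4class{GapPenalty} or
#'   \linkS4class{ScoringScheme}.
#' @return \code{scoreTable} returns the full integer score table (including
#'   the trailing zero row/column for the dummy code); \code{matrixName} the
#'   matrix label; \code{gapOpen}/\code{gapExtend} the affine gap penalties
#'   in score points.
#' @name scoring-accessors
#' @examples
#' s <- scoringScheme("BLOSUM62", "10-2k")
#' gapOpen(s); gapExtend(s); matrixName(s)
NULL

#' @describeIn scoring-accessors Score table of a matrix.
#' @export
setMethod("scoreTable", "SubstitutionMatrix", function(x) x@scores)

#' @describeIn scoring-accessors Score table of a scheme's matrix.
#' @export
setMethod("scoreTable", "ScoringScheme", function(x) x@matrix@scores)

#' @describeIn scoring-accessors Name of a substitution matrix.
#' @export
setMethod("matrixName", "SubstitutionMatrix", function(x) x@name)

#' @describeIn scoring-accessors Name of a scheme's matrix.
#' @export
setMethod("matrixName", "ScoringScheme", function(x) x@matrix@name)

#' @describeIn scoring-accessors Gap-open penalty.
#' @export
setMethod("gapOpen", "GapPenalty", function(x) x@open)

#' @describeIn scoring-accessors Gap-extension penalty.
#' @export
setMethod("gapExtend", "GapPenalty", function(x) x@extend)

#' @describeIn scoring-accessors Gap-open penalty of a scheme.
#' @export
setMethod("gapOpen", "ScoringScheme", function(x) x@gap@open)

#' @describeIn scoring-accessors Gap-extension penalty of a scheme.
#' @export
setMethod("gapExtend", "ScoringScheme", function(x) x@gap@extend)

setMethod("show", "SubstitutionMatrix", function(object) {
    cat(sprintf("SubstitutionMatrix '%s': %d symbols (%s%s)\n",
                object@name, length(object@alphabet@symbols),
                paste(head(object@alphabet@symbols, 8L), collapse = ""),
                if (length(object@alphabet@symbols) > 8L) "..." else ""))
    invisible(object)
})

setMethod("show", "GapPenalty", function(object) {
    cat(sprintf("GapPenalty: open %d, extend %d (a length-k gap costs %d + %d k)\n",
                object@open, object@extend, object@open, object@extend))
    invisible(object)
})

setMethod("show", "ScoringScheme", function(object) {
    cat(sprintf("ScoringScheme: %s, gap %d-%dk\n", object@matrix@name,
                object@gap@open, object@gap@extend))
    invisible(object)
})

## Parse an NCBI-layout score-matrix file: '#' lines are comments, the first
## non-comment line is the column alphabet, each following line is a row
## label plus one integer per column.
.parseNcbiMatrix <- function(path, name) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) < 2L)
        stop("matrix file '", path, "' has no score rows", call. = FALSE)
    cols <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
    rows <- strsplit(lines[-1L], "[[:space:]]+")
    labels <- vapply(rows, `[`, "", 1L)
    vals <- lapply(rows, function(r) suppressWarnings(as.integer(r[-1L])))
    if (any(vapply(vals, anyNA, TRUE)))
        stop("matrix file '", path, "' contains non-integer scores",
             call. = FALSE)
    if (any(lengths(vals) != length(cols)))
        stop("matrix file '", path, "' is not square: a row does not have ",
             "one score per alphabet column", call. = FALSE)
    if (length(labels) != length(cols) || !identical(labels, cols))
        stop("matrix file '", path, "' is not square: row labels do not ",
             "match the column alphabet", call. = FALSE)
    m <- do.call(rbind, vals)
    dimnames(m) <- list(labels, cols)
    asym <- which(m != t(m), arr.ind = TRUE)
    if (nrow(asym) > 0L)
        stop(sprintf(
            "matrix '%s' is asymmetric at pair (%s, %s): %d vs %d",
            name, labels[asym[1L, 1L]], labels[asym[1L, 2L]],
            m[asym[1L, , drop = FALSE]], t(m)[asym[1L, , drop = FALSE]]),
            call. = FALSE)
    m
}

#' Load a substitution matrix
#'
#' Loads one of the built-in BLOSUM matrices (\code{"BLOSUM62"},
#' \code{"BLOSUM50"}, with the standard published integer scores of the
#' NCBI matrix files) or a user-supplied file in NCBI score-matrix text
#' layout.  The table must be square and symmetric; an asymmetric table is
#' rejected with an error naming the offending residue pair.  A dummy
#' padding code scoring 0 against everything is appended to the alphabet.
#'
#' @param name Matrix name (\code{"BLOSUM62"} or \code{"BLOSUM50"}) or the
#'   path of a readable NCBI-layout matrix file.
#' @return A \linkS4class{SubstitutionMatrix}.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' scoreTable(m)[1, 1]  # score of (A, A): 4
#' @export
loadMatrix <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    if (toupper(name) %in% .BUILTIN_MATRICES) {
        label <- toupper(name)
        path <- system.file("extdata", paste0(label, ".txt"),
                            package = "swstripe", mustWork = TRUE)
    } else if (file.exists(name)) {
        label <- name
        path <- name
    } else {
        stop("unknown substitution matrix '", name, "': not a built-in (",
             paste(.BUILTIN_MATRICES, collapse = ", "),
             ") and not a readable file", call. = FALSE)
    }
    m <- .parseNcbiMatrix(path, label)
    k <- nrow(m)
    full <- matrix(0L, k + 1L, k + 1L)
    full[seq_len(k), seq_len(k)] <- m
    ab <- Alphabet(rownames(m))
    dimnames(full) <- list(c(rownames(m), "."), c(colnames(m), "."))
    new("SubstitutionMatrix", name = label, scores = full, alphabet = ab)
}

#' Parse a gap-penalty specification
#'
#' Accepts the common search-tool shorthand \code{"<q>-<r>k"} (a gap of
#' length k costs q + r*k; whitespace before the \code{k} is tolerated) or
#' the explicit form \code{"<q>/<r>"}.  The extension penalty must be at
#' least 1.
#'
#' @param spec Character gap specification, e.g. \code{"10-2k"}.
#' @return A \linkS4class{GapPenalty}.
#' @examples
#' parseGapSpec("10-2k")   # open 10, extend 2
#' parseGapSpec("40-3 k")  # open 40, extend 3
#' @export
parseGapSpec <- function(spec) {
    stopifnot(is.character(spec), length(spec) == 1L)
    s <- trimws(spec)
    m <- regmatches(s, regexec("^([0-9]+)[[:space:]]*-[[:space:]]*([0-9]+)[[:space:]]*k$", s))[[1L]]
    if (length(m) == 0L)
        m <- regmatches(s, regexec("^([0-9]+)[[:space:]]*/[[:space:]]*([0-9]+)$", s))[[1L]]
    if (length(m) == 0L)
        stop("malformed gap specification '", spec,
             "': expected \"<open>-<extend>k\" or \"<open>/<extend>\"",
             call. = FALSE)
    gapPenalty(as.integer(m[2L]), as.integer(m[3L]))
}

#' Construct an affine gap penalty
#'
#' @param open Non-negative gap-open penalty (score points).
#' @param extend Gap-extension penalty (score points), at least 1.
#' @return A \linkS4class{GapPenalty}.
#' @export
gapPenalty <- function(open, extend) {
    new("GapPenalty", open = as.integer(open), extend = as.integer(extend))
}

#' Construct a scoring scheme
#'
#' @param matrix A \linkS4class{SubstitutionMatrix}, or a name/path accepted
#'   by \code{\link{loadMatrix}}.
#' @param gap A \linkS4class{GapPenalty}, or a specification string accepted
#'   by \code{\link{parseGapSpec}}.
#' @return A \linkS4class{ScoringScheme}.
#' @examples
#' scoringScheme("BLOSUM62", "10-2k")
#' scoringScheme(loadMatrix("BLOSUM50"), gapPenalty(0, 8))
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gap = "10-2k") {
    if (is.character(matrix)) matrix <- loadMatrix(matrix)
    if (is.character(gap)) gap <- parseGapSpec(gap)
    stopifnot(is(matrix, "SubstitutionMatrix"), is(gap, "GapPenalty"))
    new("ScoringScheme", matrix = matrix, gap = gap)
}

#' Encode a residue string as integer codes
#'
#' Case-insensitive; whitespace and translation stops (\code{*}) are
#' stripped.  By default characters absent from the alphabet map to the code
#' of \code{X} when the matrix carries an \code{X} row (the usual
#' unknown-residue convention of protein search tools), otherwise to the
#' dummy code; with \code{strict = TRUE} unknown characters are an error.
#'
#' @param x Character string of residues (or an already-encoded integer
#'   vector, returned unchanged).
#' @param scheme A \linkS4class{ScoringScheme}, \linkS4class{SubstitutionMatrix}
#'   or \linkS4class{Alphabet} providing the symbol-to-code mapping.
#' @param strict Promote unknown characters to an error.
#' @return Integer vector of residue codes.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' encodeSequence("acgt", m)
#' encodeSequence("A A*", m)   # stripping: codes of A, A
#' @export
encodeSequence <- function(x, scheme, strict = FALSE) {
    if (is.numeric(x)) return(as.integer(x))
    ab <- if (is(scheme, "Alphabet")) scheme else alphabet(scheme)
    stopifnot(is.character(x), length(x) == 1L)
    chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    chars <- chars[!(chars %in% c("*", " ", "\t", "\n", "\r"))]
    if (length(chars) == 0L) return(integer(0L))
    codes <- match(chars, ab@symbols)
    unknown <- is.na(codes)
    if (any(unknown)) {
        if (strict)
            stop("unknown residue character(s): ",
                 paste(unique(chars[unknown]), collapse = ", "),
                 call. = FALSE)
        xcode <- match("X", ab@symbols)
        codes[unknown] <- if (is.na(xcode)) dummyCode(ab) else xcode
    }
    codes
}

#' Decode residue codes back to a string
#'
#' Inverse of \code{\link{encodeSequence}} for in-alphabet codes; the dummy
#' code decodes to \code{"."}.
#'
#' @inheritParams encodeSequence
#' @param codes Integer residue codes.
#' @return Character string.
#' @export
decodeSequence <- function(codes, scheme) {
    ab <- if (is(scheme, "Alphabet")) scheme else alphabet(scheme)
    syms <- c(ab@symbols, ".")
    if (any(codes < 1L | codes > length(syms)))
        stop("residue code out of range", call. = FALSE)
    paste(syms[codes], collapse = "")
}
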