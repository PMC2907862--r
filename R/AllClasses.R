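#' @import methods
#' @importFrom stats runif rgeom
#' @importFrom utils head
NULL

#' Residue alphabet with a reserved padding code
#'
#' An ordered set of residue symbols (the 20 standard amino acids plus any
#' ambiguity letters carried by the substitution matrix, such as B, Z, X or
#' \code{*}) together with one reserved \emph{dummy} code.  Symbols are
#' encoded as the integers \code{1..length(symbols)}; the dummy code is
#' \code{length(symbols) + 1} and scores 0 against every residue, so that
#' padding a sequence with dummies can never change an alignment score.
#'
#' @slot symbols Character vector of single-character residue symbols.
#' @aliases Alphabet
#' @exportClass Alphabet
setClass("Alphabet", representation(symbols = "character"))

setValidity("Alphabet", function(object) {
    s <- object@symbols
    if (length(s) < 1L) return("alphabet must contain at least one symbol")
    if (any(nchar(s) != 1L)) return("alphabet symbols must be single characters")
    if (anyDuplicated(s)) {
        return(sprintf("duplicated alphabet symbol: '%s'",
                       s[duplicated(s)][1L]))
    }
    TRUE
})

#' Integer substitution matrix over a residue alphabet
#'
#' A symmetric, square integer score table indexed by residue-code pairs.
#' The stored table has one extra trailing row and column for the alphabet's
#' dummy (padding) code, which scores 0 against everything.
#'
#' @slot name Label, e.g. \code{"BLOSUM62"} or a file path.
#' @slot scores Integer matrix of dimension \code{(K+1) x (K+1)} where
#'   \code{K} is the alphabet size; entry \code{[a, b]} is the substitution
#'   score (in score points) of residue codes \code{a} and \code{b}.
#' @slot alphabet An \linkS4class{Alphabet}.
#' @aliases SubstitutionMatrix
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
         representation(name = "character", scores = "matrix",
                        alphabet = "Alphabet"))

setValidity("SubstitutionMatrix", function(object) {
    sc <- object@scores
    k <- length(object@alphabet@symbols)
    if (!is.integer(sc)) return("scores must be an integer matrix")
    if (nrow(sc) != ncol(sc)) return("scores must be square")
    if (nrow(sc) != k + 1L) {
        return("scores must cover every alphabet code plus the dummy code")
    }
    asym <- which(sc != t(sc), arr.ind = TRUE)
    if (nrow(asym) > 0L) {
        lab <- c(object@alphabet@symbols, "<dummy>")
        return(sprintf("matrix is not symmetric at pair (%s, %s): %d vs %d",
                       lab[asym[1L, 1L]], lab[asym[1L, 2L]],
                       sc[asym[1L, , drop = FALSE]],
                       t(sc)[asym[1L, , drop = FALSE]]))
    }
    if (any(sc[k + 1L, ] != 0L) || any(sc[, k + 1L] != 0L)) {
        return("dummy residue must score 0 against every residue")
    }
    TRUE
})

#' Affine gap penalty
#'
#' Affine gap costs: a gap of length \code{k} costs
#' \code{open + k * extend} score points, so the first gapped cell costs
#' \code{open + extend}.  The extension penalty must be strictly positive:
#' the vectorized engines rely on a strictly decaying vertical-gap score to
#' terminate their lazy-F correction loop and to make zero a safe fill value
#' for lane shifts.
#'
#' @slot open Non-negative integer gap-open penalty (score points).
#' @slot extend Positive integer gap-extension penalty (score points).
#' @aliases GapPenalty
#' @exportClass GapPenalty
setClass("GapPenalty", representation(open = "integer", extend = "integer"))

setValidity("GapPenalty", function(object) {
    if (length(object@open) != 1L || is.na(object@open) || object@open < 0L)
        return("gap open penalty must be a single non-negative integer")
    if (length(object@extend) != 1L || is.na(object@extend) ||
        object@extend < 1L)
        return("gap extension penalty must be a single integer >= 1")
    TRUE
})

#' Complete scoring scheme
#'
#' Bundles a substitution matrix (with its alphabet) and an affine gap
#' penalty; every alignment engine takes one of these.
#'
#' @slot matrix A \linkS4class{SubstitutionMatrix}.
#' @slot gap A \linkS4class{GapPenalty}.
#' @aliases ScoringScheme
#' @exportClass ScoringScheme
setClass("ScoringScheme",
         representation(matrix = "SubstitutionMatrix", gap = "GapPenalty"))

#' Sequential query profile
#'
#' Pre-computed substitution scores between every alphabet residue and every
#' query position: row \code{r}, column \code{i} holds
#' \code{sbt(r, Q[i])}.  Padded positions (dummy residues) score 0 against
#' every residue.
#'
#' @slot queryLength Query length before any padding.
#' @slot values Integer matrix, one row per residue code (including the
#'   dummy code) and one column per (possibly padded) query position.
#' @aliases SequentialProfile
#' @exportClass SequentialProfile
setClass("SequentialProfile",
         representation(queryLength = "integer", values = "matrix"))

#' Striped query profile
#'
#' The query is padded to \code{T * VL} positions (\code{T = ceiling(l/VL)})
#' and its profile is reordered into \code{VL} interleaved lanes: lane
#' \code{v}, segment \code{s} holds the score of query position
#' \code{v*T + s} (0-based), so that SIMD lanes process equally spaced query
#' positions and the only cross-lane dependency is the vertical-gap (F)
#' carry handled by the lazy-F loop.
#'
#' @slot queryLength Query length before padding.
#' @slot vl Lane count (virtual vector length).
#' @slot segments Segment count \code{T = ceiling(queryLength / vl)}.
#' @slot values Integer array of dimension \code{c(vl, segments, nres)};
#'   \code{values[v, s, r]} is the score of residue \code{r} against query
#'   position \code{(v-1)*T + s} (1-based), 0 at padded positions.
#' @aliases StripedProfile
#' @exportClass StripedProfile
setClass("StripedProfile",
         representation(queryLength = "integer", vl = "integer",
                        segments = "integer", values = "array"))

setValidity("StripedProfile", function(object) {
    if (object@vl < 1L) return("vl must be >= 1")
    tt <- (object@queryLength + object@vl - 1L) %/% object@vl
    if (object@segments != tt)
        return("segments must equal ceiling(queryLength / vl)")
    d <- dim(object@values)
    if (length(d) != 3L || d[1L] != object@vl || d[2L] != object@segments)
        return("values must be a vl x segments x nres array")
    TRUE
})

#' Fixed-width virtual SIMD vector
#'
#' Emulates one virtualized SIMD vector of \code{VL} integer lanes.  By
#' convention lane 0 is the logical rightmost element, so a left shift moves
#' values toward higher lane indices.  Lanes are stored with lane 0 first.
#'
#' @slot lanes Integer vector of lane values (lane 0 first).
#' @aliases VirtualVector
#' @exportClass VirtualVector
setClass("VirtualVector", representation(lanes = "integer"))

setValidity("VirtualVector", function(object) {
    if (length(object@lanes) < 1L) return("a vector needs at least one lane")
    if (anyNA(object@lanes)) return("lane values must not be NA")
    TRUE
})

#' Query partition plan
#'
#' The query split into consecutive partitions of exactly \code{PL} residues
#' (the last one padded with dummy residues), each with its own striped
#' profile of \code{T = PL / VL} segments.  \code{PL} must be a multiple of
#' \code{VL}.
#'
#' @slot queryLength Query length before padding.
#' @slot pl Partition length (residues).
#' @slot vl Lane count.
#' @slot partitions List of integer code vectors, each of length \code{pl}.
#' @slot profiles List of \linkS4class{StripedProfile}, one per partition.
#' @aliases PartitionPlan
#' @exportClass PartitionPlan
setClass("PartitionPlan",
         representation(queryLength = "integer", pl = "integer",
                        vl = "integer", partitions = "list",
                        profiles = "list"))

setValidity("PartitionPlan", function(object) {
    if (object@pl < object@vl || object@pl %% object@vl != 0L)
        return("partition length must be a positive multiple of the lane count")
    if (length(object@partitions) != length(object@profiles))
        return("one profile is required per partition")
    if (any(vapply(object@partitions, length, 1L) != object@pl))
        return("every partition must have exactly pl residue codes")
    TRUE
})

#' Ranked database-search result
#'
#' Ranked subject sequences with their optimal local alignment scores, plus
#' run metadata (engine, scheme, cell count, elapsed scoring time, GCUPS).
#' Scores are non-increasing with rank; ties keep database input order.
#'
#' @slot hits A data.frame with columns \code{rank}, \code{subject_id},
#'   \code{subject_length} and \code{score}.
#' @slot metadata Named list of run metadata.
#' @aliases SearchResult
#' @exportClass SearchResult
setClass("SearchResult",
         representation(hits = "data.frame", metadata = "list"))

setValidity("SearchResult", function(object) {
    h <- object@hits
    need <- c("rank", "subject_id", "subject_length", "score")
    if (!all(need %in% names(h)))
        return(paste("hits must have columns", paste(need, collapse = ", ")))
    if (is.unsorted(rev(h$score))) return("scores must be non-increasing")
    TRUE
})

#' Synthetic database specification
#'
#' Describes a reproducible synthetic protein database: record count, a
#' length law (\code{fixed}, \code{uniform} or \code{logUniform}), a seed
#' and a residue composition.  The same specification always regenerates a
#' byte-identical FASTA file.
#'
#' @slot nRecords Number of records.
#' @slot lengthLaw One of \code{"fixed"}, \code{"uniform"},
#'   \code{"logUniform"}.
#' @slot lengthA First length parameter (fixed length, or lower bound).
#' @slot lengthB Second length parameter (upper bound; ignored for
#'   \code{fixed}).
#' @slot seed Integer seed.
#' @slot composition Named numeric vector of residue frequencies.
#' @aliases FixtureSpec
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(nRecords = "integer", lengthLaw = "character",
                        lengthA = "integer", lengthB = "integer",
                        seed = "integer", composition = "numeric"))

setValidity("FixtureSpec", function(object) {
    if (object@nRecords < 1L) return("nRecords must be >= 1")
    if (!object@lengthLaw %in% c("fixed", "uniform", "logUniform"))
        return("lengthLaw must be 'fixed', 'uniform' or 'logUniform'")
    if (object@lengthA < 0L) return("lengths must be non-negative")
    if (object@lengthLaw != "fixed" && object@lengthB < object@lengthA)
        return("upper length bound must be >= lower bound")
    if (abs(sum(object@composition) - 1) > 1e-8)
        return("composition must sum to 1")
    TRUE
})
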