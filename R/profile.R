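## Sequential and striped query profiles.

#' Number of striped segments for a query
#'
#' The striped layout divides a (padded) query of length \code{l} into
#' \code{VL} equal lanes of \code{T} consecutive positions each, with
#' \code{T = ceiling(l / VL) = (l + VL - 1) \%/\% VL}.
#'
#' @param l Query length (>= 1).
#' @param vl Lane count (>= 1).
#' @return Integer segment count \code{T}.
#' @examples
#' segmentCount(16, 4)  # 4
#' segmentCount(17, 4)  # 5
#' @export
segmentCount <- function(l, vl) {
    l <- as.integer(l); vl <- as.integer(vl)
    if (length(l) != 1L || is.na(l) || l < 1L)
        stop("query length must be a positive integer", call. = FALSE)
    if (length(vl) != 1L || is.na(vl) || vl < 1L)
        stop("lane count must be a positive integer", call. = FALSE)
    (l + vl - 1L) %/% vl
}

.padQuery <- function(codes, toLength, dummy) {
    if (length(codes) < toLength)
        codes <- c(codes, rep.int(dummy, toLength - length(codes)))
    codes
}

#' Build a sequential query profile
#'
#' For every alphabet residue r and query position i the profile holds
#' \code{sbt(r, Q[i])}, replacing substitution-matrix lookups in the
#' alignment inner loop.  Optionally the query is padded with dummy
#' residues (score 0 against everything) to a multiple of \code{padTo}.
#'
#' @param query Residue string or integer code vector.
#' @param matrix A \linkS4class{SubstitutionMatrix} (or
#'   \linkS4class{ScoringScheme}).
#' @param padTo Optional: pad the query with dummy residues to a multiple of
#'   this length (e.g. a vector length); 0 disables padding.
#' @return A \linkS4class{SequentialProfile}.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' p <- buildSequentialProfile("AC", m)
#' profileValues(p)["A", ]  # 4 0
#' @export
buildSequentialProfile <- function(query, matrix, padTo = 0L) {
    if (is(matrix, "ScoringScheme")) matrix <- matrix@matrix
    q <- encodeSequence(query, matrix)
    if (length(q) == 0L) stop("query must be non-empty", call. = FALSE)
    padTo <- as.integer(padTo)
    if (padTo > 0L && length(q) %% padTo != 0L)
        qp <- .padQuery(q, segmentCount(length(q), padTo) * padTo,
                        dummyCode(matrix))
    else qp <- q
    vals <- scoreTable(matrix)[, qp, drop = FALSE]
    colnames(vals) <- NULL
    new("SequentialProfile", queryLength = length(q), values = vals)
}

#' Build a striped query profile
#'
#' The query is padded with dummy residues to \code{T * VL} positions
#' (\code{T = ceiling(l/VL)}) and reordered into \code{VL} interleaved
#' lanes: lane v, segment s holds \code{sbt(r, Q[v*T + s])} (0-based), 0 at
#' padded positions.  With \code{vl = 1} the striped profile reduces to the
#' sequential one.
#'
#' @inheritParams buildSequentialProfile
#' @param vl Lane count (>= 1).
#' @return A \linkS4class{StripedProfile}.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' sp <- buildStripedProfile("HEAGAWGH", m, vl = 4)
#' segmentCountOf(sp)  # 2
#' @export
buildStripedProfile <- function(query, matrix, vl) {
    if (is(matrix, "ScoringScheme")) matrix <- matrix@matrix
    q <- encodeSequence(query, matrix)
    if (length(q) == 0L) stop("query must be non-empty", call. = FALSE)
    vl <- as.integer(vl)
    tt <- segmentCount(length(q), vl)
    qp <- .padQuery(q, tt * vl, dummyCode(matrix))
    sq <- scoreTable(matrix)[, qp, drop = FALSE]   # residues x positions
    nres <- nrow(sq)
    ## query position of (lane v, segment s), both 1-based: (v-1)*T + s
    idx <- matrix(seq_len(tt * vl), nrow = vl, byrow = TRUE)
    arr <- array(t(sq)[as.vector(idx), ], dim = c(vl, tt, nres))
    new("StripedProfile", queryLength = length(q), vl = vl,
        segments = tt, values = arr)
}

#' Profile accessors
#'
#' @param x A \linkS4class{SequentialProfile} or
#'   \linkS4class{StripedProfile}.
#' @return \code{queryLength}: unpadded query length; \code{laneCount}: lane
#'   count VL; \code{segmentCountOf}: segment count T;
#'   \code{profileValues}: the underlying integer matrix/array (rows named
#'   by residue symbol for sequential profiles).
#' @name profile-accessors
NULL

#' @describeIn profile-accessors Unpadded query length.
#' @export
setMethod("queryLength", "SequentialProfile", function(x) x@queryLength)

#' @describeIn profile-accessors Unpadded query length.
#' @export
setMethod("queryLength", "StripedProfile", function(x) x@queryLength)

#' @describeIn profile-accessors Lane count of a striped profile.
#' @export
setMethod("laneCount", "StripedProfile", function(x) x@vl)

#' @describeIn profile-accessors Segment count of a striped profile.
#' @export
setMethod("segmentCountOf", "StripedProfile", function(x) x@segments)

#' @describeIn profile-accessors Residue-by-position score matrix.
#' @export
setMethod("profileValues", "SequentialProfile", function(x) x@values)

#' @describeIn profile-accessors Lane-by-segment-by-residue score array.
#' @export
setMethod("profileValues", "StripedProfile", function(x) x@values)

setMethod("show", "StripedProfile", function(object) {
    cat(sprintf("StripedProfile: query length %d, VL %d, T %d (%d padded positions)\n",
                object@queryLength, object@vl, object@segments,
                object@vl * object@segments - object@queryLength))
    invisible(object)
})

## lane-major (VL x T) matrix -> vector in query order
.deStripeMatrix <- function(m) as.vector(t(m))

#' @describeIn deStripe A \code{VL x T} lane-by-segment matrix becomes the
#'   length-\code{T*VL} vector in query order.
#' @export
setMethod("deStripe", "matrix", function(x, ...) .deStripeMatrix(x))

#' @describeIn deStripe A striped profile becomes the equivalent
#'   \linkS4class{SequentialProfile} restricted to the real query positions.
#' @export
setMethod("deStripe", "StripedProfile", function(x, ...) {
    vl <- x@vl; tt <- x@segments; nres <- dim(x@values)[3L]
    flat <- matrix(x@values, nrow = vl * tt, ncol = nres)  # (v,s) col-major
    ## row of (v,s) in flat is v + (s-1)*vl; query position is (v-1)*tt + s
    v <- rep(seq_len(vl), times = tt)
    s <- rep(seq_len(tt), each = vl)
    ord <- order((v - 1L) * tt + s)
    vals <- t(flat[ord, , drop = FALSE])[, seq_len(x@queryLength), drop = FALSE]
    new("SequentialProfile", queryLength = x@queryLength,
        values = matrix(as.integer(vals), nrow = nres))
})
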