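## Emulation of the virtualized SIMD lane machine: fixed-width lane vectors,
## shifts, lane-predicate votes, and saturating arithmetic built from
## max/min.  Lane 0 is the logical rightmost element, so a left shift moves
## values toward higher lane indices.

#' Construct a virtual SIMD vector
#'
#' @param lanes Integer lane values, lane 0 (the logical rightmost element)
#'   first.
#' @return A \linkS4class{VirtualVector}.
#' @examples
#' v <- virtualVector(c(1, 2, 3, 4))
#' lanes(shiftLeft(v, 1))  # 0 1 2 3
#' @export
virtualVector <- function(lanes) {
    new("VirtualVector", lanes = as.integer(lanes))
}

#' Lane values of a virtual vector
#' @param x A \linkS4class{VirtualVector}.
#' @return Integer vector of lane values (lane 0 first).
#' @export
lanes <- function(x) {
    stopifnot(is(x, "VirtualVector"))
    x@lanes
}

#' @describeIn profile-accessors Lane count of a virtual vector.
#' @export
setMethod("laneCount", "VirtualVector", function(x) length(x@lanes))

setMethod("show", "VirtualVector", function(object) {
    cat(sprintf("VirtualVector (VL = %d, lane 0 rightmost): [%s]\n",
                length(object@lanes),
                paste(rev(object@lanes), collapse = " ")))
    invisible(object)
})

## plain-vector core used by the alignment engines (lane 0 is element 1)
.shiftLeft <- function(x, n, fill) {
    vl <- length(x)
    if (n == 0L) return(x)
    if (n >= vl) return(rep.int(fill, vl))
    c(rep.int(fill, n), x[seq_len(vl - n)])
}

.checkShift <- function(n, vl) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 0L || n > vl)
        stop("shift count must be between 0 and the lane count", call. = FALSE)
    n
}

.satClamp <- function(x, floor, ceiling) {
    x <- pmin(pmax(x, floor), ceiling)
    if (all(abs(x) <= .Machine$integer.max)) x <- as.integer(x)
    x
}

#' Virtual SIMD lane operations
#'
#' \code{shiftLeft} shifts a vector \code{n} lanes to the left (toward
#' higher lane indices, given the rightmost-lane-0 convention): result lane
#' k takes the value of lane k - n, and the vacated low lanes take
#' \code{fill}.  \code{allLanes}/\code{anyLanes} are the warp-vote predicate
#' reductions over a per-lane logical vector.  \code{satAdd}/\code{satSub}
#' are lane-wise saturating addition/subtraction, clamped into the score
#' range \code{[floor, ceiling]} with max/min; with the default 32-bit range
#' the clamp is unreachable at realistic alignment scores and the
#' operations reduce to plain arithmetic.
#'
#' @param x,y A \linkS4class{VirtualVector} or plain integer lane vector
#'   (lane 0 first); for the votes, a logical per-lane vector.
#' @param n Shift count, between 0 and the lane count.
#' @param fill Value shifted into vacated lanes.
#' @param floor,ceiling Saturation bounds of the score range.
#' @return \code{shiftLeft}, \code{satAdd}, \code{satSub}: an object of the
#'   same kind as \code{x}; \code{allLanes}, \code{anyLanes}: a single
#'   logical.
#' @name simd-ops
#' @examples
#' shiftLeft(c(5L, 6L, 7L, 8L), 1, fill = 0)  # 0 5 6 7
#' allLanes(c(TRUE, TRUE))                    # TRUE
#' satSub(c(0L, 3L), 2L, floor = 0)           # 0 1
NULL

#' @rdname simd-ops
#' @export
setMethod("shiftLeft", "VirtualVector", function(x, n = 1L, fill = 0L) {
    n <- .checkShift(n, length(x@lanes))
    virtualVector(.shiftLeft(x@lanes, n, as.integer(fill)))
})

#' @rdname simd-ops
#' @export
setMethod("shiftLeft", "numeric", function(x, n = 1L, fill = 0L) {
    n <- .checkShift(n, length(x))
    .shiftLeft(as.integer(x), n, as.integer(fill))
})

#' @rdname simd-ops
#' @export
setMethod("allLanes", "logical", function(x) {
    if (anyNA(x)) stop("lane predicate must not contain NA", call. = FALSE)
    all(x)
})

#' @rdname simd-ops
#' @export
setMethod("anyLanes", "logical", function(x) {
    if (anyNA(x)) stop("lane predicate must not contain NA", call. = FALSE)
    any(x)
})

#' @rdname simd-ops
#' @export
setMethod("satAdd", signature("numeric", "numeric"),
          function(x, y, floor = -.Machine$integer.max,
                   ceiling = .Machine$integer.max) {
    .satClamp(as.numeric(x) + as.numeric(y), floor, ceiling)
})

#' @rdname simd-ops
#' @export
setMethod("satSub", signature("numeric", "numeric"),
          function(x, y, floor = -.Machine$integer.max,
                   ceiling = .Machine$integer.max) {
    .satClamp(as.numeric(x) - as.numeric(y), floor, ceiling)
})

#' @rdname simd-ops
#' @export
setMethod("satAdd", signature("VirtualVector", "VirtualVector"),
          function(x, y, floor = -.Machine$integer.max,
                   ceiling = .Machine$integer.max) {
    stopifnot(length(x@lanes) == length(y@lanes))
    virtualVector(.satClamp(as.numeric(x@lanes) + as.numeric(y@lanes),
                            floor, ceiling))
})

#' @rdname simd-ops
#' @export
setMethod("satSub", signature("VirtualVector", "VirtualVector"),
          function(x, y, floor = -.Machine$integer.max,
                   ceiling = .Machine$integer.max) {
    stopifnot(length(x@lanes) == length(y@lanes))
    virtualVector(.satClamp(as.numeric(x@lanes) - as.numeric(y@lanes),
                            floor, ceiling))
})
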