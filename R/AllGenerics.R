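#' @rdname alphabet-accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname alphabet-accessors
#' @export
setGeneric("alphabetSymbols", function(x) standardGeneric("alphabetSymbols"))

#' @rdname alphabet-accessors
#' @export
setGeneric("dummyCode", function(x) standardGeneric("dummyCode"))

#' @rdname scoring-accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoring-accessors
#' @export
setGeneric("matrixName", function(x) standardGeneric("matrixName"))

#' @rdname scoring-accessors
#' @export
setGeneric("gapOpen", function(x) standardGeneric("gapOpen"))

#' @rdname scoring-accessors
#' @export
setGeneric("gapExtend", function(x) standardGeneric("gapExtend"))

#' @rdname profile-accessors
#' @export
setGeneric("queryLength", function(x) standardGeneric("queryLength"))

#' @rdname profile-accessors
#' @export
setGeneric("laneCount", function(x) standardGeneric("laneCount"))

#' @rdname profile-accessors
#' @export
setGeneric("segmentCountOf", function(x) standardGeneric("segmentCountOf"))

#' @rdname profile-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' De-stripe a lane-major object back to query order
#'
#' Inverse of the striped mapping: lane \code{v}, segment \code{s} maps back
#' to query position \code{v*T + s} (0-based).  For a \code{VL x T} matrix
#' this returns a vector of length \code{T*VL} in query order; for a
#' \linkS4class{StripedProfile} it returns the equivalent
#' \linkS4class{SequentialProfile} restricted to the real (unpadded) query
#' positions.
#'
#' @param x Object to de-stripe.
#' @param ... Further arguments for methods.
#' @return See method descriptions.
#' @export
setGeneric("deStripe", function(x, ...) standardGeneric("deStripe"))

#' @rdname simd-ops
#' @export
setGeneric("shiftLeft", function(x, n = 1L, fill = 0L)
    standardGeneric("shiftLeft"))

#' @rdname simd-ops
#' @export
setGeneric("allLanes", function(x) standardGeneric("allLanes"))

#' @rdname simd-ops
#' @export
setGeneric("anyLanes", function(x) standardGeneric("anyLanes"))

#' @rdname simd-ops
#' @export
setGeneric("satAdd", function(x, y, floor = -.Machine$integer.max,
                              ceiling = .Machine$integer.max)
    standardGeneric("satAdd"))

#' @rdname simd-ops
#' @export
setGeneric("satSub", function(x, y, floor = -.Machine$integer.max,
                              ceiling = .Machine$integer.max)
    standardGeneric("satSub"))

#' @rdname SearchResult-accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname SearchResult-accessors
#' @export
setGeneric("searchMetadata", function(x) standardGeneric("searchMetadata"))

#' @rdname SearchResult-accessors
#' @export
setGeneric("gcups", function(x) standardGeneric("gcups"))
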