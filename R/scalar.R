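## Scalar reference Smith-Waterman engine: the correctness oracle for the
## vectorized engines.

#' @useDynLib swstripe, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.encodePair <- function(query, subject, scheme) {
    stopifnot(is(scheme, "ScoringScheme"))
    q <- encodeSequence(query, scheme)
    s <- encodeSequence(subject, scheme)
    if (length(q) == 0L || length(s) == 0L)
        stop("query and subject must be non-empty after encoding",
             call. = FALSE)
    list(q = q, s = s)
}

## Alignment scores are held as 32-bit signed integers; refuse inputs whose
## best possible score could approach the representable limit.
.checkOverflow <- function(q, s, scheme) {
    maxsub <- max(scoreTable(scheme))
    bound <- as.numeric(min(length(q), length(s))) * max(maxsub, 1L)
    if (bound > .Machine$integer.max / 4)
        stop("alignment score could overflow 32-bit integer range",
             call. = FALSE)
    invisible(TRUE)
}

#' Scalar Smith-Waterman local alignment score
#'
#' Reference implementation of the affine-gap Smith-Waterman recurrence:
#' \deqn{H_{i,j} = \max(0,\; H_{i-1,j-1} + sbt(S_1[i], S_2[j]),\; E_{i,j},\; F_{i,j})}
#' \deqn{E_{i,j} = \max(H_{i,j-1} - \rho - \sigma,\; E_{i,j-1} - \sigma)}
#' \deqn{F_{i,j} = \max(H_{i-1,j} - \rho - \sigma,\; F_{i-1,j} - \sigma)}
#' initialized with zeros on the boundary row and column.  The returned
#' score is the maximum over all cells of H.  Only H is clamped at zero;
#' E and F are carried as signed integers.
#'
#' @param query,subject Residue strings or integer code vectors.
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return Integer optimal local alignment score.
#' @examples
#' s50 <- scoringScheme("BLOSUM50", gapPenalty(0, 8))
#' swScore("HEAGAWGHEE", "PAWHEAE", s50)  # 28
#' @export
swScore <- function(query, subject, scheme) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    sw_score_cpp(p$q, p$s, scoreTable(scheme),
                 gapOpen(scheme) + gapExtend(scheme), gapExtend(scheme))
}

#' Full Smith-Waterman dynamic-programming tables
#'
#' Exposes the complete H, E and F tables of the scalar engine (shape
#' \code{(l1+1) x (l2+1)} including the zero boundary row/column), for
#' column-level validation of the vectorized engines.
#'
#' @inheritParams swScore
#' @return A list with integer matrices \code{H}, \code{E}, \code{F} and
#'   the scalar \code{best} (equal to \code{swScore} on the same inputs).
#' @export
swFull <- function(query, subject, scheme) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    sw_full_cpp(p$q, p$s, scoreTable(scheme),
                gapOpen(scheme) + gapExtend(scheme), gapExtend(scheme))
}
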