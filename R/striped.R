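## Basic vectorized Smith-Waterman: striped inner loop over T segments plus
## the lazy-F correction loop, executed on the emulated virtual SIMD lane
## machine.
##
## Per subject column the inner loop visits the T segments sequentially,
## postulating that vertical-gap (F) contributions beyond the current lane
## run do not contribute; the lazy-F phase then shifts the column-final F
## vector one lane to the left and re-applies F segment by segment (with
## wrap-around) until the lane vote says no stored H can change.  After
## finalization the de-striped H and E columns equal the scalar engine's
## columns cell-for-cell; no such guarantee holds for F.

#' Per-column state of the striped engine
#'
#' Holds the striped H and E values of the current column (lane-by-segment
#' matrices), the running best score, the last observed F value of the
#' column's final cell, and the number of lazy-F correction steps taken for
#' the last processed column.
#'
#' @slot H,E Integer \code{VL x T} matrices of striped H and E values.
#' @slot best Running maximum H over all processed cells.
#' @slot lastF Observed F value at the column's last cell (possibly stale;
#'   see \code{\link{carryBoundary}}).
#' @slot lazySteps Lazy-F steps taken in the last column.
#' @aliases ColumnState
#' @exportClass ColumnState
setClass("ColumnState",
         representation(H = "matrix", E = "matrix", best = "integer",
                        lastF = "integer", lazySteps = "integer"))

#' Create an empty column state
#'
#' @param vl Lane count.
#' @param segments Segment count T.
#' @param scheme A \linkS4class{ScoringScheme} (its extension penalty seeds
#'   the E state: before the first column every E value equals
#'   \code{-extend}, the exact signed E of column 1).
#' @return A \linkS4class{ColumnState}.
#' @export
columnState <- function(vl, segments, scheme) {
    vl <- as.integer(vl); segments <- as.integer(segments)
    new("ColumnState",
        H = matrix(0L, vl, segments),
        E = matrix(-gapExtend(scheme), vl, segments),
        best = 0L, lastF = -.Machine$integer.max, lazySteps = 0L)
}

## "no path" sentinel for the F stream: far below any reachable score, so
## it can never trigger the lazy-F vote nor pollute an observed F value.
.NEG_INF <- -536870912L

#' Lazy-F continuation predicate
#'
#' The lane vote deciding whether the lazy-F loop must keep correcting:
#' continue while any lane's F value exceeds \code{H - open} of the stored
#' H at the current segment.  A lane with \code{F > H} still has to raise
#' H; a lane with \code{H - open < F <= H} can still carry a dominating
#' downstream F (\code{F - extend > H - open - extend}, i.e. its decayed
#' value beats the gap opened from the stored H).  Once \code{F <= H - open}
#' everywhere, every further contribution of the vector is dominated by a
#' gap opened from an already-correct H, so H, E and the boundary F carry
#' are all final.
#'
#' @param vF Integer lane vector of F values.
#' @param vH Integer lane vector of stored H values at the current segment.
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return \code{TRUE} to continue correcting, \code{FALSE} to exit.
#' @export
lazyFPredicate <- function(vF, vH, scheme) {
    stopifnot(length(vF) == length(vH))
    anyLanes(vF > vH - gapOpen(scheme))
}

## One column of the striped algorithm, in place on plain matrices.
## vH/vE enter holding the previous column's finalized state; P is the
## VL x T profile column; diag0 is the H boundary entering lane 0 segment 1
## (matrix boundary or previous partition's H at column j-1); f0 is the F
## entering the first row (matrix boundary or partition carry).
## Returns the finalized state plus the observed last-cell F and the lazy
## step count.
.processColumn <- function(vH, vE, P, vl, tt, goe, ge, rho, diag0, f0,
                           forceFull = FALSE) {
    prevT <- vH[, tt]
    vX <- c(diag0, prevT[seq_len(vl - 1L)])
    ## lane 0 enters with the exact first-row F (boundary or carry); the
    ## other lanes' incoming F is unknown until the lazy phase, represented
    ## by the "no path" sentinel so no phantom gap path is injected
    vF <- rep.int(.NEG_INF, vl)
    vF[1L] <- f0
    fobs <- .NEG_INF
    colMax <- 0L
    for (s in seq_len(tt)) {
        vDiag <- vX + P[, s]
        vX <- vH[, s]
        e <- vE[, s]
        h <- pmax.int(vDiag, e, vF, 0L)
        vH[, s] <- h
        if (s == tt) fobs <- vF[vl]
        m <- max(h)
        if (m > colMax) colMax <- m
        hg <- h - goe
        vE[, s] <- pmax.int(hg, e - ge)
        vF <- pmax.int(hg, vF - ge)
    }
    ## lazy-F correction: shift F one lane left (lane 0 takes the sentinel,
    ## its boundary F having been seeded exactly in the inner loop) and
    ## sweep segments with wrap-around until the vote exits
    vF <- c(.NEG_INF, vF[seq_len(vl - 1L)])
    s <- 1L
    steps <- 0L
    maxSteps <- tt * vl   # after VL wraps every original lane value is gone
    repeat {
        if (forceFull) {
            if (steps >= maxSteps) break
        } else {
            if (!any(vF > vH[, s] - rho)) break
        }
        h2 <- pmax.int(vH[, s], vF)
        vH[, s] <- h2
        vE[, s] <- pmax.int(vE[, s], h2 - goe)
        m <- max(h2)
        if (m > colMax) colMax <- m
        if (s == tt && vF[vl] > fobs) fobs <- vF[vl]
        vF <- vF - ge
        steps <- steps + 1L
        s <- s + 1L
        if (s > tt) {
            s <- 1L
            vF <- c(.NEG_INF, vF[seq_len(vl - 1L)])
        }
    }
    list(H = vH, E = vE, colMax = colMax, lastF = fobs, lazySteps = steps)
}

#' Process one subject column of the striped algorithm
#'
#' Advances a \linkS4class{ColumnState} by one subject position: the inner
#' loop over the T segments (which postulates that cross-lane F values do
#' not contribute), followed by the lazy-F correction loop.  Exposed for
#' validation and instrumentation; \code{\link{stripedSwScore}} drives it
#' over whole sequences.
#'
#' @param state A \linkS4class{ColumnState}.
#' @param profileColumn \code{VL x T} integer matrix: the striped profile
#'   scores of the current subject residue
#'   (\code{profileValues(sp)[, , code]}).
#' @param scheme A \linkS4class{ScoringScheme}.
#' @param diagIn H value entering the diagonal path of lane 0, segment 1
#'   (0 at the matrix boundary; the previous partition's H at the previous
#'   column when partitioning).
#' @param fIn F value entering the first query row (\code{NULL} for the
#'   matrix boundary, which evaluates to \code{-extend}; the partition
#'   carry otherwise).
#' @param forceFull Run the lazy-F loop to full correction (re-evaluating
#'   every cell) instead of exiting on the lane vote; the finalized column
#'   is identical either way.
#' @return The updated \linkS4class{ColumnState}.
#' @export
processColumn <- function(state, profileColumn, scheme, diagIn = 0L,
                          fIn = NULL, forceFull = FALSE) {
    stopifnot(is(state, "ColumnState"), is(scheme, "ScoringScheme"))
    if (is.null(fIn)) fIn <- -gapExtend(scheme)
    vl <- nrow(state@H); tt <- ncol(state@H)
    if (!is.matrix(profileColumn) || nrow(profileColumn) != vl ||
        ncol(profileColumn) != tt)
        stop("profileColumn must be a VL x T matrix matching the state",
             call. = FALSE)
    r <- .processColumn(state@H, state@E, profileColumn, vl, tt,
                        gapOpen(scheme) + gapExtend(scheme),
                        gapExtend(scheme), gapOpen(scheme),
                        as.integer(diagIn), as.integer(fIn), forceFull)
    new("ColumnState", H = r$H, E = r$E,
        best = max(state@best, r$colMax),
        lastF = r$lastF, lazySteps = r$lazySteps)
}

## Column sweep of one striped profile over a whole subject.
## carryH[j]: previous partition's finalized H at column j (diagonal input
## for the first striped row at column j+1); carryF[j]: F entering the
## first row at column j.  When emitCarry, returns the same two arrays for
## the next partition.  collectRows > 0 additionally returns the de-striped
## H and E columns restricted to the first collectRows rows (H finalized,
## E as it entered the column).
.stripedSweep <- function(prof, vl, tt, subject, goe, ge, rho,
                          carryH = NULL, carryF = NULL, emitCarry = FALSE,
                          collectRows = 0L, collectFirstRowE = FALSE,
                          forceFull = FALSE) {
    l2 <- length(subject)
    vH <- matrix(0L, vl, tt)
    vE <- matrix(-ge, vl, tt)
    best <- 0L
    lazyFull <- logical(l2)
    HlastOut <- if (emitCarry) integer(l2) else NULL
    FnextOut <- if (emitCarry) integer(l2) else NULL
    Hcols <- if (collectRows > 0L) matrix(0L, collectRows, l2) else NULL
    Ecols <- if (collectRows > 0L) matrix(0L, collectRows, l2) else NULL
    firstRowE <- if (collectFirstRowE) integer(l2) else NULL
    rowSel <- if (collectRows > 0L) seq_len(collectRows) else NULL
    for (j in seq_len(l2)) {
        P <- prof[, , subject[j]]
        dim(P) <- c(vl, tt)
        diag0 <- if (j == 1L || is.null(carryH)) 0L else carryH[j - 1L]
        ## matrix-boundary first-row F: max(H(0,j) - open - extend,
        ## F(0,j) - extend) = -extend
        f0 <- if (is.null(carryF)) -ge else carryF[j]
        if (collectRows > 0L)
            Ecols[, j] <- .deStripeMatrix(vE)[rowSel]
        if (collectFirstRowE)
            firstRowE[j] <- vE[1L, 1L]
        r <- .processColumn(vH, vE, P, vl, tt, goe, ge, rho, diag0, f0,
                            forceFull)
        vH <- r$H; vE <- r$E
        if (r$colMax > best) best <- r$colMax
        lazyFull[j] <- forceFull || r$lazySteps >= tt
        if (emitCarry) {
            HlastOut[j] <- vH[vl, tt]
            FnextOut[j] <- max(HlastOut[j] - goe, r$lastF - ge)
        }
        if (collectRows > 0L)
            Hcols[, j] <- .deStripeMatrix(vH)[rowSel]
    }
    list(best = best, lazyFull = lazyFull, HlastOut = HlastOut,
         FnextOut = FnextOut, Hcols = Hcols, Ecols = Ecols,
         firstRowE = firstRowE)
}

#' Striped vectorized Smith-Waterman score
#'
#' The basic vectorized algorithm: the query profile is laid out in
#' \code{vl} interleaved lanes and each subject column is computed by a
#' striped inner loop over the \code{T} segments followed by a lazy-F
#' correction loop with a lane-vote early exit.  The returned score equals
#' \code{\link{swScore}} on the same inputs for every lane count -- that
#' equality is the engine's defining contract.
#'
#' @inheritParams swScore
#' @param vl Lane count of the virtual SIMD vector (any integer >= 1).
#' @return Integer optimal local alignment score.
#' @examples
#' s50 <- scoringScheme("BLOSUM50", gapPenalty(0, 8))
#' stripedSwScore("HEAGAWGHEE", "PAWHEAE", s50, vl = 4)  # 28
#' @export
stripedSwScore <- function(query, subject, scheme, vl = 16L) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    vl <- as.integer(vl)
    sp <- buildStripedProfile(p$q, scheme@matrix, vl)
    r <- .stripedSweep(sp@values, vl, sp@segments, p$s,
                       gapOpen(scheme) + gapExtend(scheme),
                       gapExtend(scheme), gapOpen(scheme))
    r$best
}

#' Striped-engine columns for validation
#'
#' Runs the striped engine and returns, for every subject column, the
#' de-striped H column after finalization and the E column as it entered
#' the column (both restricted to the real query rows), together with the
#' score and a per-column flag saying whether the lazy-F loop ran a full
#' correction pass (at least T steps) or exited early.  The H and E
#' matrices are cell-for-cell identical to the scalar engine's
#' \code{\link{swFull}} tables (columns \code{1..l2}, rows \code{1..l1}).
#'
#' @inheritParams stripedSwScore
#' @param forceFull Run every lazy-F loop to full correction; the finalized
#'   columns are identical to the early-exit ones.
#' @return A list with \code{H} and \code{E} (integer \code{l1 x l2}
#'   matrices), \code{score}, and logical \code{lazyFull} of length
#'   \code{l2}.
#' @export
stripedAlignmentColumns <- function(query, subject, scheme, vl = 16L,
                                    forceFull = FALSE) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    vl <- as.integer(vl)
    sp <- buildStripedProfile(p$q, scheme@matrix, vl)
    r <- .stripedSweep(sp@values, vl, sp@segments, p$s,
                       gapOpen(scheme) + gapExtend(scheme),
                       gapExtend(scheme), gapOpen(scheme),
                       collectRows = length(p$q), forceFull = forceFull)
    list(H = r$Hcols, E = r$Ecols, score = r$best, lazyFull = r$lazyFull)
}
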