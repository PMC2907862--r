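## Partitioned vectorized Smith-Waterman: the query is split into
## consecutive PL-length partitions, each aligned with the striped engine,
## with per-column H/F boundary values carried from one partition to the
## next.  The carried F is the F of the NEXT partition's first cell,
## computed as max(H_last - open - extend, F_last - extend); this is exact
## even when the lazy-F loop left a stale F in the last lane, because
## whenever the loop exits early the stale F satisfies
## F_last - extend <= H_last - open - extend and the (always correct)
## H path dominates.

#' Split a query into striped partitions
#'
#' Divides the query into consecutive partitions of exactly \code{pl}
#' residues (the last one padded with zero-scoring dummy residues) and
#' builds one striped profile of \code{T = pl/vl} segments per partition.
#' \code{pl} must be a multiple of \code{vl}.
#'
#' @param query Residue string or integer code vector.
#' @param matrix A \linkS4class{SubstitutionMatrix} (or
#'   \linkS4class{ScoringScheme}).
#' @param pl Partition length in residues.
#' @param vl Lane count.
#' @return A \linkS4class{PartitionPlan}.
#' @examples
#' m <- loadMatrix("BLOSUM62")
#' plan <- partitionQuery(randomProtein(600, seed = 1), m, pl = 256, vl = 16)
#' length(plan@partitions)  # 3
#' @export
partitionQuery <- function(query, matrix, pl = 256L, vl = 16L) {
    if (is(matrix, "ScoringScheme")) matrix <- matrix@matrix
    q <- encodeSequence(query, matrix)
    if (length(q) == 0L) stop("query must be non-empty", call. = FALSE)
    pl <- as.integer(pl); vl <- as.integer(vl)
    if (vl < 1L || pl < vl || pl %% vl != 0L)
        stop("partition length (", pl, ") must be a positive multiple of ",
             "the lane count (", vl, ")", call. = FALSE)
    n <- segmentCount(length(q), pl)
    dummy <- dummyCode(matrix)
    parts <- lapply(seq_len(n), function(p) {
        .padQuery(q[seq.int((p - 1L) * pl + 1L,
                            min(p * pl, length(q)))], pl, dummy)
    })
    profs <- lapply(parts, buildStripedProfile, matrix = matrix, vl = vl)
    new("PartitionPlan", queryLength = length(q), pl = pl, vl = vl,
        partitions = parts, profiles = profs)
}

#' Boundary F carry between query partitions
#'
#' The F value of the first cell of the next partition, computed from the H
#' and F values of the last cell of the current partition:
#' \code{max(H - open - extend, F - extend)}.  The result is correct even
#' when \code{fLast} is stale (left over from an early-exiting lazy-F
#' loop): early exit implies \code{F - extend <= H - open - extend}, so the
#' H path -- which is always exact -- dominates.
#'
#' @param hLast H value(s) of the last cell of the current partition's
#'   column (vectorized over columns).
#' @param fLast Observed F value(s) of the same cell.
#' @param gap A \linkS4class{GapPenalty} (or \linkS4class{ScoringScheme}).
#' @return Integer F value(s) entering the next partition's first row.
#' @examples
#' g <- gapPenalty(10, 2)
#' carryBoundary(20, 5, g)  # max(20 - 12, 5 - 2) = 8
#' carryBoundary(0, 0, g)   # -12: a negative carry never raises an H
#' @export
carryBoundary <- function(hLast, fLast, gap) {
    if (is(gap, "ScoringScheme")) gap <- gap@gap
    stopifnot(is(gap, "GapPenalty"))
    pmax.int(as.integer(hLast) - gap@open - gap@extend,
             as.integer(fLast) - gap@extend)
}

## Shared driver: run the striped engine partition by partition, handing
## the per-column boundary carries forward.
.partitionedSweep <- function(plan, subject, goe, ge, rho, trace = FALSE) {
    nP <- length(plan@profiles)
    tt <- plan@pl %/% plan@vl
    carryH <- NULL
    carryF <- NULL
    best <- 0L
    boundaries <- if (trace) vector("list", nP - 1L) else NULL
    firstRowE <- if (trace) matrix(0L, nP, length(subject)) else NULL
    for (p in seq_len(nP)) {
        r <- .stripedSweep(plan@profiles[[p]]@values, plan@vl, tt, subject,
                           goe, ge, rho, carryH = carryH, carryF = carryF,
                           emitCarry = (p < nP || trace),
                           collectFirstRowE = trace)
        if (r$best > best) best <- r$best
        if (trace) {
            firstRowE[p, ] <- r$firstRowE
            if (p < nP)
                boundaries[[p]] <- list(Hlast = r$HlastOut,
                                        Fnext = r$FnextOut,
                                        lazyFull = r$lazyFull)
        }
        carryH <- r$HlastOut
        carryF <- r$FnextOut
    }
    list(best = best, boundaries = boundaries, firstRowE = firstRowE)
}

#' Partitioned vectorized Smith-Waterman score
#'
#' Splits the query into \code{pl}-length partitions, aligns the subject
#' against each partition with the striped engine, and carries per-column H
#' and F boundary values between partitions (the diagonal input of a
#' partition's first row at column j is the previous partition's H at
#' column j-1; the vertical input is the carried first-row F at column j).
#' The returned score equals \code{\link{swScore}} on the same inputs for
#' every valid (pl, vl) combination.  Defaults: \code{pl = 256},
#' \code{vl = 16}.
#'
#' @inheritParams swScore
#' @param pl Partition length (a multiple of \code{vl}).
#' @param vl Lane count.
#' @return Integer optimal local alignment score.
#' @examples
#' s50 <- scoringScheme("BLOSUM50", gapPenalty(0, 8))
#' partitionedSwScore("HEAGAWGHEE", "PAWHEAE", s50, pl = 4, vl = 2)  # 28
#' @export
partitionedSwScore <- function(query, subject, scheme, pl = 256L, vl = 16L) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    plan <- partitionQuery(p$q, scheme@matrix, pl = pl, vl = vl)
    r <- .partitionedSweep(plan, p$s,
                           gapOpen(scheme) + gapExtend(scheme),
                           gapExtend(scheme), gapOpen(scheme))
    r$best
}

#' Partitioned-engine boundary trace for validation
#'
#' Runs the partitioned engine with instrumentation and returns, for every
#' partition boundary, the per-column H of the partition's last row, the
#' carried first-row F of the next partition, and a per-column flag saying
#' whether the lazy-F loop of that column ran a full correction pass
#' (case 1) or exited early with a possibly stale last-lane F (case 2).
#' In both cases the carried F equals the true F of the next partition's
#' first row in \code{\link{swFull}}.  Also records the E value entering
#' each partition's first row per column, which is independent of the
#' partitioning because E carries no cross-row state.
#'
#' @inheritParams partitionedSwScore
#' @return A list with \code{score}, \code{nPartitions}, \code{boundaries}
#'   (a list with one element per boundary, each holding integer vectors
#'   \code{Hlast} and \code{Fnext} and logical \code{lazyFull}, all indexed
#'   by subject column), and \code{firstRowE} (an
#'   \code{nPartitions x l2} integer matrix).
#' @export
partitionedAlignmentTrace <- function(query, subject, scheme, pl = 256L,
                                      vl = 16L) {
    p <- .encodePair(query, subject, scheme)
    .checkOverflow(p$q, p$s, scheme)
    plan <- partitionQuery(p$q, scheme@matrix, pl = pl, vl = vl)
    r <- .partitionedSweep(plan, p$s,
                           gapOpen(scheme) + gapExtend(scheme),
                           gapExtend(scheme), gapOpen(scheme), trace = TRUE)
    list(score = r$best, nPartitions = length(plan@profiles),
         boundaries = r$boundaries, firstRowE = r$firstRowE)
}
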