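## Database-search driver: read FASTA, score every subject with a chosen
## engine, rank, and report GCUPS throughput.

#' Read a FASTA protein database
#'
#' Standard FASTA parsing (via Biostrings): \code{>} begins a header,
#' sequence lines are concatenated, blank lines ignored.  Translation stops
#' (\code{*}) and whitespace are stripped from the sequences; records that
#' are empty after stripping are dropped with a warning.
#'
#' @param path Path of a readable FASTA file.
#' @return A named character vector of upper-case sequences; names are the
#'   full header lines.
#' @export
readFastaDb <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path, call. = FALSE)
    x <- Biostrings::readAAStringSet(path)
    if (length(x) == 0L)
        stop("FASTA file contains no records: ", path, call. = FALSE)
    seqs <- toupper(gsub("[*[:space:]]", "", as.character(x)))
    names(seqs) <- names(x)
    empty <- !nzchar(seqs)
    if (any(empty)) {
        warning(sum(empty), " empty record(s) dropped: ",
                paste(sub(" .*", "", names(seqs)[empty]), collapse = ", "),
                call. = FALSE)
        seqs <- seqs[!empty]
    }
    if (length(seqs) == 0L)
        stop("no non-empty records in ", path, call. = FALSE)
    seqs
}

#' Cell updates per second, in billions
#'
#' The standard throughput metric for alignment engines: dynamic-programming
#' cell updates per second divided by 1e9, where the cell count of a search
#' is query length times total subject residues.
#'
#' @param cellCount Number of DP cells updated.
#' @param elapsed Elapsed time in seconds (> 0).
#' @return GCUPS as a double.
#' @examples
#' computeGcups(1e9, 1)  # 1
#' @export
computeGcups <- function(cellCount, elapsed) {
    stopifnot(is.numeric(cellCount), is.numeric(elapsed),
              length(elapsed) == 1L)
    if (elapsed <= 0) stop("elapsed time must be positive", call. = FALSE)
    as.numeric(cellCount) / elapsed / 1e9
}

#' Search a protein database
#'
#' Scores one query against every subject of a database with the selected
#' engine and returns the top-k subjects ranked by optimal local alignment
#' score (ties keep database input order).  All three engines produce
#' identical rankings and scores on identical inputs.
#'
#' @param query Query sequence: a character string, or a path/named vector
#'   as for \code{db} (first record used).
#' @param db Database: a named character vector of sequences (as returned
#'   by \code{\link{readFastaDb}} or \code{\link{generateDatabase}}) or the
#'   path of a FASTA file.
#' @param scheme A \linkS4class{ScoringScheme}.
#' @param engine \code{"scalar"}, \code{"striped"} or \code{"partitioned"}.
#' @param vl Lane count for the vectorized engines.
#' @param pl Partition length for the partitioned engine (multiple of
#'   \code{vl}).
#' @param topk Number of hits to report (clamped to the database size).
#' @return A \linkS4class{SearchResult}.
#' @examples
#' db <- generateDatabase(fixtureSpec(5, "fixed", 60, seed = 7))
#' res <- searchDatabase(db[[1]], db, scoringScheme("BLOSUM62", "10-2k"))
#' hits(res)
#' @export
searchDatabase <- function(query, db, scheme = scoringScheme(),
                           engine = c("scalar", "striped", "partitioned"),
                           vl = 16L, pl = 256L, topk = 10L) {
    engine <- match.arg(engine)
    stopifnot(is(scheme, "ScoringScheme"))
    if (is.character(db) && length(db) == 1L && is.null(names(db)) &&
        file.exists(db))
        db <- readFastaDb(db)
    if (length(db) == 0L) stop("database is empty", call. = FALSE)
    if (is.character(query) && length(query) == 1L && file.exists(query))
        query <- readFastaDb(query)[1L]
    vl <- as.integer(vl); pl <- as.integer(pl)
    if (engine == "partitioned" && (vl < 1L || pl %% vl != 0L))
        stop("partition length must be a multiple of the lane count",
             call. = FALSE)
    if (engine == "striped" && vl < 1L)
        stop("lane count must be >= 1", call. = FALSE)

    q <- encodeSequence(query, scheme)
    if (length(q) == 0L) stop("query is empty after encoding", call. = FALSE)
    subjects <- lapply(unname(db), encodeSequence, scheme = scheme)
    keep <- lengths(subjects) > 0L
    if (!all(keep)) {
        warning(sum(!keep), " empty subject(s) dropped", call. = FALSE)
        db <- db[keep]; subjects <- subjects[keep]
    }
    ids <- if (is.null(names(db))) sprintf("subject_%d", seq_along(db))
           else sub("[[:space:]].*", "", names(db))
    lens <- lengths(subjects)
    cells <- as.numeric(length(q)) * sum(as.numeric(lens))

    goe <- gapOpen(scheme) + gapExtend(scheme)
    ge <- gapExtend(scheme); rho <- gapOpen(scheme)
    t0 <- proc.time()[["elapsed"]]
    scores <- switch(engine,
        scalar = {
            .checkOverflow(q, subjects[[which.max(lens)]], scheme)
            as.integer(sw_score_batch_cpp(q, subjects, scoreTable(scheme),
                                          goe, ge))
        },
        striped = {
            sp <- buildStripedProfile(q, scheme@matrix, vl)
            vapply(subjects, function(s)
                .stripedSweep(sp@values, vl, sp@segments, s, goe, ge,
                              rho)$best, 1L)
        },
        partitioned = {
            plan <- partitionQuery(q, scheme@matrix, pl = pl, vl = vl)
            vapply(subjects, function(s)
                .partitionedSweep(plan, s, goe, ge, rho)$best, 1L)
        })
    elapsed <- proc.time()[["elapsed"]] - t0

    ord <- order(scores, decreasing = TRUE, method = "radix")
    topk <- min(as.integer(topk), length(ord))
    sel <- ord[seq_len(topk)]
    hitsDf <- data.frame(rank = seq_len(topk), subject_id = ids[sel],
                         subject_length = as.integer(lens[sel]),
                         score = as.integer(scores[sel]),
                         stringsAsFactors = FALSE)
    meta <- list(engine = engine, matrix = matrixName(scheme),
                 gap = sprintf("%d-%dk", gapOpen(scheme), gapExtend(scheme)),
                 vl = if (engine == "scalar") NA_integer_ else vl,
                 pl = if (engine == "partitioned") pl else NA_integer_,
                 queryLength = length(q), nSubjects = length(subjects),
                 cellCount = cells, elapsed = elapsed,
                 gcups = if (elapsed > 0) computeGcups(cells, elapsed)
                         else NA_real_)
    new("SearchResult", hits = hitsDf, metadata = meta)
}

#' Search-result accessors
#'
#' @param x A \linkS4class{SearchResult}.
#' @return \code{hits}: the ranked hit table; \code{searchMetadata}: the
#'   metadata list; \code{gcups}: the measured throughput in billions of
#'   cell updates per second.
#' @name SearchResult-accessors
NULL

#' @describeIn SearchResult-accessors Ranked hit table.
#' @export
setMethod("hits", "SearchResult", function(x) x@hits)

#' @describeIn SearchResult-accessors Metadata list.
#' @export
setMethod("searchMetadata", "SearchResult", function(x) x@metadata)

#' @describeIn SearchResult-accessors Measured GCUPS.
#' @export
setMethod("gcups", "SearchResult", function(x) x@metadata$gcups)

setMethod("show", "SearchResult", function(object) {
    m <- object@metadata
    cat(sprintf("SearchResult: %s engine, %s %s, query %d aa vs %d subjects\n",
                m$engine, m$matrix, m$gap, m$queryLength, m$nSubjects))
    cat(sprintf("  %.0f cells in %.3f s (%.4f GCUPS)\n", m$cellCount,
                m$elapsed, ifelse(is.na(m$gcups), 0, m$gcups)))
    print(head(object@hits, 10L), row.names = FALSE)
    invisible(object)
})
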