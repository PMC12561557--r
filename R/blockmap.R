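## Internal: blocks of one chromosome as an IRanges (1-based closed,
## converted from the 0-based half-open internal convention).
.blockRanges <- function(df)
    IRanges::IRanges(start = df$ref_start + 1, end = df$ref_end)

## Internal: accept a BlockSet or an already-grouped list.
.asGrouped <- function(x) {
    if (is(x, "BlockSet")) groupBlocks(x) else x
}

#' Group alignment blocks by chromosome
#'
#' Partitions a [BlockSet-class] into one table per reference
#' chromosome, each sorted by (`ref_start`, `ref_end`) with a stable
#' sort; chromosomes are ordered by name.  Every input block appears
#' in exactly one group.
#'
#' @param x A [BlockSet-class].
#' @return Named list of data.frames (one per chromosome).
#' @export
groupBlocks <- function(x) {
    b <- blocks(x)
    if (nrow(b) == 0L)
        return(structure(list(), names = character()))
    groups <- split(b, b$ref_name)
    groups <- groups[order(names(groups))]
    lapply(groups, function(g) {
        g <- g[order(g$ref_start, g$ref_end), , drop = FALSE]
        rownames(g) <- NULL
        g
    })
}

#' Annotate alignment blocks
#'
#' For every block, computes its reference/query lengths, the signed
#' reference-coordinate distance to the next block on the chromosome
#' (`gap_to_next`, negative when neighbours overlap, `NA` for the last
#' block), the colinear run it belongs to, whether its reference
#' interval is also covered by a block from a different contig
#' (`repeat_flag`), and a category for each of its two ends.
#'
#' End categories, in order of precedence:
#' \describe{
#'   \item{chromosome_terminus}{the block touches reference position 0
#'     or the chromosome end.}
#'   \item{contig_terminus}{the corresponding query coordinate touches
#'     0 or the contig length (respecting orientation).}
#'   \item{overlaps_neighbour}{the adjacent reference gap is negative.}
#'   \item{abuts_gap}{the adjacent reference gap (including the
#'     unaligned margin before the first and after the last block) is
#'     at least `minUncovered`.}
#'   \item{alignment_break}{none of the above.}
#' }
#'
#' @param x A [BlockSet-class] or the output of [groupBlocks()].
#' @param contigLengths Contig sequences or named length vector.
#' @param chromLengths Reference sequences or named length vector.
#' @param config An [EvalConfig-class].
#' @return A data.frame, one row per block in chromosome order.
#' @export
annotateBlocks <- function(x, contigLengths, chromLengths,
                           config = evalConfig()) {
    grouped <- .asGrouped(x)
    qlens <- seqLens(contigLengths)
    clens <- seqLens(chromLengths)
    runs <- findColinearRuns(grouped, config)
    runOf <- setNames(rep(runs$run_id, runs$n_blocks),
                      unlist(strsplit(runs$block_ids, ",", fixed = TRUE)))
    out <- list()
    for (chrom in names(grouped)) {
        g <- grouped[[chrom]]
        if (!chrom %in% names(clens))
            stop("unknown chromosome '", chrom, "'")
        unknownQ <- setdiff(unique(g$query_name), names(qlens))
        if (length(unknownQ))
            stop("unknown contig '", unknownQ[1L], "'")
        clen <- clens[[chrom]]
        n <- nrow(g)
        gapNext <- c(g$ref_start[-1L] - g$ref_end[-n], NA_real_)
        ## classification gaps: margins to the chromosome termini stand
        ## in for the missing neighbour of the first/last block
        leftGap <- c(g$ref_start[1L], gapNext[-n])
        rightGap <- gapNext
        rightGap[n] <- clen - g$ref_end[n]
        qlen <- qlens[g$query_name]
        fwd <- g$orientation == "+"
        touchL <- ifelse(fwd, g$query_start == 0, g$query_end == qlen)
        touchR <- ifelse(fwd, g$query_end == qlen, g$query_start == 0)
        classify <- function(chromTerm, contigTerm, gap) {
            ifelse(chromTerm, "chromosome_terminus",
            ifelse(contigTerm, "contig_terminus",
            ifelse(!is.na(gap) & gap < 0, "overlaps_neighbour",
            ifelse(!is.na(gap) & gap >= config@minUncovered, "abuts_gap",
                   "alignment_break"))))
        }
        leftEnd <- classify(g$ref_start == 0, touchL, leftGap)
        rightEnd <- classify(g$ref_end == clen, touchR, rightGap)
        ## repeat_flag: overlap with a block of a different contig
        ir <- .blockRanges(g)
        hits <- IRanges::findOverlaps(ir, ir)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        other <- qh != sh & g$query_name[qh] != g$query_name[sh]
        repFlag <- seq_len(n) %in% qh[other]
        out[[chrom]] <- data.frame(
            block_id = g$block_id, ref_name = g$ref_name,
            query_name = g$query_name,
            ref_len = g$ref_end - g$ref_start,
            query_len = g$query_end - g$query_start,
            left_end = leftEnd, right_end = rightEnd,
            gap_to_next = gapNext,
            run_id = unname(runOf[g$block_id]),
            repeat_flag = repFlag, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res))
        res <- data.frame(block_id = character(), ref_name = character(),
                          query_name = character(), ref_len = numeric(),
                          query_len = numeric(), left_end = character(),
                          right_end = character(), gap_to_next = numeric(),
                          run_id = character(), repeat_flag = logical())
    res
}

#' Find colinear runs of alignment blocks
#'
#' Chains blocks greedily left-to-right along each chromosome: the
#' current run is extended with the next block exactly when it comes
#' from the same contig with the same orientation, starts at or after
#' the end of the previous block with a reference gap of at most
#' `colinearGapTol`, and its query coordinates progress in the
#' direction the orientation implies (ascending for forward runs,
#' descending for reverse runs).  Otherwise a new run starts.  Every
#' block belongs to exactly one run.
#'
#' @inheritParams annotateBlocks
#' @return A data.frame with one row per run: `run_id`, `chrom`,
#'   `query_name`, `orientation`, `n_blocks`, `ref_start`, `ref_end`,
#'   `query_start`, `query_end` and the comma-separated `block_ids`.
#' @export
findColinearRuns <- function(x, config = evalConfig()) {
    grouped <- .asGrouped(x)
    rows <- list()
    for (chrom in names(grouped)) {
        g <- grouped[[chrom]]
        counter <- 0L
        cur <- NULL
        flush <- function() {
            if (is.null(cur)) return()
            counter <<- counter + 1L
            rows[[length(rows) + 1L]] <<- data.frame(
                run_id = sprintf("%s_run%04d", chrom, counter),
                chrom = chrom, query_name = cur$query,
                orientation = cur$orientation,
                n_blocks = length(cur$ids),
                ref_start = cur$refStart, ref_end = cur$refEnd,
                query_start = cur$qMin, query_end = cur$qMax,
                block_ids = paste(cur$ids, collapse = ","),
                stringsAsFactors = FALSE)
        }
        for (i in seq_len(nrow(g))) {
            b <- g[i, ]
            extend <- FALSE
            if (!is.null(cur)) {
                gap <- b$ref_start - cur$refEnd
                sameCtx <- b$query_name == cur$query &&
                    b$orientation == cur$orientation
                colinearGap <- gap >= 0 && gap <= config@colinearGapTol
                qProgress <- if (b$orientation == "+")
                    b$query_start >= cur$lastQEnd
                else
                    b$query_end <= cur$lastQStart
                extend <- sameCtx && colinearGap && qProgress
            }
            if (extend) {
                cur$ids <- c(cur$ids, b$block_id)
                cur$refEnd <- b$ref_end
                cur$qMin <- min(cur$qMin, b$query_start)
                cur$qMax <- max(cur$qMax, b$query_end)
                cur$lastQStart <- b$query_start
                cur$lastQEnd <- b$query_end
            } else {
                flush()
                cur <- list(query = b$query_name,
                            orientation = b$orientation,
                            ids = b$block_id, refStart = b$ref_start,
                            refEnd = b$ref_end, qMin = b$query_start,
                            qMax = b$query_end,
                            lastQStart = b$query_start,
                            lastQEnd = b$query_end)
            }
        }
        flush()
    }
    if (length(rows) == 0L)
        return(data.frame(run_id = character(), chrom = character(),
                          query_name = character(),
                          orientation = character(), n_blocks = integer(),
                          ref_start = numeric(), ref_end = numeric(),
                          query_start = numeric(), query_end = numeric(),
                          block_ids = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect inverted segments
#'
#' A reverse-orientation colinear run whose contig also produces
#' forward runs both before and after it (in reference order, on the
#' same chromosome) is reported as an inversion spanning the run's
#' reference interval — the opposite-slope segment of a dotplot.  A
#' reverse run with no same-contig forward context is still reported,
#' flagged as lower confidence: without flanks, a wholly
#' reverse-complemented contig is indistinguishable from an inversion.
#'
#' @param runs Output of [findColinearRuns()].
#' @return A data.frame: `chrom`, `start`, `end`, `length`,
#'   `query_name`, `confidence` ("flanked" or "isolated").
#' @export
detectInversions <- function(runs) {
    out <- list()
    for (chrom in unique(runs$chrom)) {
        rc <- runs[runs$chrom == chrom, , drop = FALSE]
        rc <- rc[order(rc$ref_start, rc$ref_end), , drop = FALSE]
        rev <- which(rc$orientation == "-")
        for (i in rev) {
            sameQ <- rc$query_name == rc$query_name[i] &
                rc$orientation == "+"
            before <- any(sameQ & rc$ref_start < rc$ref_start[i])
            after <- any(sameQ & rc$ref_start > rc$ref_start[i])
            out[[length(out) + 1L]] <- data.frame(
                chrom = chrom, start = rc$ref_start[i],
                end = rc$ref_end[i],
                length = rc$ref_end[i] - rc$ref_start[i],
                query_name = rc$query_name[i],
                confidence = if (before && after) "flanked" else "isolated",
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), length = numeric(),
                          query_name = character(),
                          confidence = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reference stretches not covered by any alignment block
#'
#' Complements the union of the block reference intervals within
#' `[0, chrom_len)` and keeps the stretches of length at least
#' `minLen` (the boundary is inclusive).  A chromosome with no blocks
#' contributes its whole length.
#'
#' @inheritParams annotateBlocks
#' @param minLen Minimum reported stretch length in bases (>= 1).
#' @return A data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `length`.
#' @export
uncoveredStretches <- function(x, chromLengths, minLen = 5000) {
    stopifnot(minLen >= 1)
    grouped <- .asGrouped(x)
    clens <- seqLens(chromLengths)
    unknown <- setdiff(names(grouped), names(clens))
    if (length(unknown))
        stop("no length for chromosome '", unknown[1L], "'")
    out <- list()
    for (chrom in names(clens)) {
        clen <- clens[[chrom]]
        g <- grouped[[chrom]]
        covered <- if (is.null(g)) IRanges::IRanges()
                   else IRanges::reduce(.blockRanges(g))
        gaps <- IRanges::setdiff(IRanges::IRanges(1, clen), covered)
        gaps <- gaps[IRanges::width(gaps) >= minLen]
        if (length(gaps))
            out[[chrom]] <- data.frame(
                chrom = chrom, start = IRanges::start(gaps) - 1,
                end = IRanges::end(gaps),
                length = as.numeric(IRanges::width(gaps)),
                stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), length = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, c(out[order(names(out))], list(make.row.names = FALSE)))
}

#' Fragmentation hotspots
#'
#' Scans each chromosome in non-overlapping windows of
#' `hotspotWindow` bases and flags windows containing at least
#' `hotspotMinInterruptions` block boundaries (starts plus ends);
#' adjacent flagged windows are merged.  Shattered repeat regions —
#' the centromeric pattern of many short multi-mapping contigs — show
#' up as dense boundary clusters.
#'
#' @inheritParams annotateBlocks
#' @return A data.frame: `chrom`, `start`, `end`, `length`,
#'   `n_boundaries`.
#' @export
fragmentationHotspots <- function(x, chromLengths,
                                  config = evalConfig()) {
    grouped <- .asGrouped(x)
    clens <- seqLens(chromLengths)
    w <- config@hotspotWindow
    out <- list()
    for (chrom in names(grouped)) {
        g <- grouped[[chrom]]
        clen <- clens[[chrom]]
        nWin <- max(1L, ceiling(clen / w))
        bounds <- c(g$ref_start, g$ref_end)
        win <- pmin(floor(bounds / w), nWin - 1L)
        counts <- tabulate(win + 1L, nbins = nWin)
        hot <- counts >= config@hotspotMinInterruptions
        if (!any(hot)) next
        r <- rle(hot)
        endIdx <- cumsum(r$lengths)
        startIdx <- endIdx - r$lengths + 1L
        for (j in which(r$values)) {
            s <- (startIdx[j] - 1L) * w
            e <- min(endIdx[j] * w, clen)
            out[[length(out) + 1L]] <- data.frame(
                chrom = chrom, start = s, end = e, length = e - s,
                n_boundaries = sum(counts[startIdx[j]:endIdx[j]]),
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), length = numeric(),
                          n_boundaries = integer(),
                          stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-chromosome mapping report
#'
#' The per-chromosome summary of a contig-to-reference mapping: the
#' aligned span, coverage of the chromosome by the union of block
#' intervals, the number of distinct mapped contigs, per-chromosome
#' L50/L90, the reference-length-weighted mean identity, and the
#' block count.
#'
#' Per-chromosome Lx is the minimal number of contigs whose summed
#' aligned reference length reaches x% of the *chromosome* length
#' (contigs taken in decreasing order of aligned length).  When even
#' all contigs together fall short of x%, Lx is set to the number of
#' contigs and the corresponding shortfall flag is raised — expected
#' for repeat-rich chromosomes whose coverage stays below 90%.
#'
#' @inheritParams annotateBlocks
#' @param xValues Percentages for the per-chromosome Lx columns.
#' @return A data.frame with one row per chromosome in `chromLengths`:
#'   `chrom`, `align_start`/`align_end` (1-based inclusive),
#'   `coverage_pct`, `n_contigs`, `l90`, `l50`, `identity_pct`,
#'   `n_blocks`, `l50_shortfall`, `l90_shortfall`.  Chromosomes with
#'   no blocks get coverage 0.
#' @export
chromosomeReport <- function(x, chromLengths, xValues = c(50, 90)) {
    grouped <- .asGrouped(x)
    clens <- seqLens(chromLengths)
    unknown <- setdiff(names(grouped), names(clens))
    if (length(unknown))
        stop("no length for chromosome '", unknown[1L], "'")
    emptyRow <- function() {
        row <- data.frame(chrom = character(), align_start = numeric(),
                          align_end = numeric(), coverage_pct = numeric(),
                          n_contigs = integer(), identity_pct = numeric(),
                          n_blocks = integer(), stringsAsFactors = FALSE)
        for (xv in xValues) {
            row[[paste0("l", xv)]] <- integer()
            row[[paste0("l", xv, "_shortfall")]] <- logical()
        }
        row
    }
    if (length(clens) == 0L)
        return(emptyRow())
    rows <- lapply(names(clens), function(chrom) {
        clen <- clens[[chrom]]
        g <- grouped[[chrom]]
        row <- data.frame(chrom = chrom, align_start = NA_real_,
                          align_end = NA_real_, coverage_pct = 0,
                          n_contigs = 0L, identity_pct = NA_real_,
                          n_blocks = 0L, stringsAsFactors = FALSE)
        for (xv in xValues) {
            row[[paste0("l", xv)]] <- 0L
            row[[paste0("l", xv, "_shortfall")]] <- TRUE
        }
        if (is.null(g) || nrow(g) == 0L)
            return(row)
        reflen <- g$ref_end - g$ref_start
        covered <- sum(IRanges::width(IRanges::reduce(.blockRanges(g))))
        row$align_start <- min(g$ref_start) + 1
        row$align_end <- max(g$ref_end)
        row$coverage_pct <- 100 * covered / clen
        row$n_contigs <- length(unique(g$query_name))
        row$identity_pct <- sum(g$identity * reflen) / sum(reflen)
        row$n_blocks <- nrow(g)
        perContig <- sort(tapply(reflen, g$query_name, sum),
                          decreasing = TRUE)
        csum <- cumsum(as.numeric(perContig))
        for (xv in xValues) {
            idx <- which(csum >= xv / 100 * clen)[1L]
            short <- is.na(idx)
            col <- paste0("l", xv)
            row[[col]] <- if (short) length(perContig) else idx
            row[[paste0(col, "_shortfall")]] <- short
        }
        row
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
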