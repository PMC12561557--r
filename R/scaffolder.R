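#' Assign contigs to reference chromosomes
#'
#' For every contig, sums its aligned reference length per chromosome
#' and assigns the contig to the chromosome carrying the largest share
#' (ties broken by chromosome name order).  A contig is left unplaced
#' when that share is below `minAssignFraction` of its total aligned
#' length, or when its total aligned length is below `minContig`.
#'
#' @param x A [BlockSet-class].
#' @param config An [EvalConfig-class].
#' @return A list with `assignments` (data.frame `query_name`,
#'   `chrom`, `assign_fraction`) and `unplaced` (character).
#' @export
assignContigs <- function(x, config = evalConfig()) {
    b <- blocks(x)
    if (nrow(b) == 0L)
        stop("no alignment blocks to assign")
    reflen <- b$ref_end - b$ref_start
    tab <- tapply(reflen, list(b$query_name, b$ref_name), sum,
                  default = 0)
    chroms <- sort(colnames(tab))
    tab <- tab[, chroms, drop = FALSE]
    rows <- list(); unplaced <- character()
    for (q in rownames(tab)) {
        aligned <- setNames(as.numeric(tab[q, ]), chroms)
        total <- sum(aligned)
        best <- chroms[which.max(aligned)]   # first max = name order
        frac <- aligned[[best]] / total
        if (frac < config@minAssignFraction || total < config@minContig) {
            unplaced <- c(unplaced, q)
        } else {
            rows[[length(rows) + 1L]] <- data.frame(
                query_name = q, chrom = best, assign_fraction = frac,
                stringsAsFactors = FALSE)
        }
    }
    assignments <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else
        data.frame(query_name = character(), chrom = character(),
                   assign_fraction = numeric(), stringsAsFactors = FALSE)
    list(assignments = assignments, unplaced = sort(unplaced))
}

#' Order and orient assigned contigs along their chromosomes
#'
#' Each contig's orientation is the aligned-length-weighted majority
#' over its blocks on the assigned chromosome (ties go to forward);
#' its anchor is the reference interval `[min ref_start, max ref_end)`
#' over the blocks of that majority orientation.  Contigs are sorted
#' by anchor midpoint (ties by name) and given consecutive 0-based
#' order indices.
#'
#' @param assignments Output of [assignContigs()].
#' @param x The [BlockSet-class] the assignment was computed from.
#' @param config An [EvalConfig-class] (stored in the result).
#' @return A [ScaffoldSet-class] with `gap_after` still `NA`.
#' @export
orderAndOrient <- function(assignments, x, config = evalConfig()) {
    b <- blocks(x)
    a <- assignments$assignments
    rows <- list()
    for (i in seq_len(nrow(a))) {
        q <- a$query_name[i]; chrom <- a$chrom[i]
        bb <- b[b$query_name == q & b$ref_name == chrom, , drop = FALSE]
        reflen <- bb$ref_end - bb$ref_start
        fwdW <- sum(reflen[bb$orientation == "+"])
        revW <- sum(reflen[bb$orientation == "-"])
        orient <- if (revW > fwdW) "-" else "+"
        anchor <- bb[bb$orientation == orient, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
            query_name = q, chrom = chrom, order_index = NA_integer_,
            orientation = orient, anchor_start = min(anchor$ref_start),
            anchor_end = max(anchor$ref_end),
            assign_fraction = a$assign_fraction[i],
            gap_after = NA_real_, stringsAsFactors = FALSE)
    }
    p <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else
        data.frame(query_name = character(), chrom = character(),
                   order_index = integer(), orientation = character(),
                   anchor_start = numeric(), anchor_end = numeric(),
                   assign_fraction = numeric(), gap_after = numeric(),
                   stringsAsFactors = FALSE)
    if (nrow(p)) {
        mid <- (p$anchor_start + p$anchor_end) / 2
        p <- p[order(p$chrom, mid, p$query_name), , drop = FALSE]
        for (chrom in unique(p$chrom))
            p$order_index[p$chrom == chrom] <-
                seq_len(sum(p$chrom == chrom)) - 1L
        rownames(p) <- NULL
    }
    new("ScaffoldSet", placements = p, unplaced = assignments$unplaced,
        config = config)
}

#' Infer inter-contig gap sizes
#'
#' The gap after placement *i* is the reference distance from its
#' anchor end to the next placement's anchor start.  When anchors abut
#' or overlap (distance <= 0) a fixed spacer of `minGapSize` N bases
#' is used instead; a positive inferred distance is kept exactly, even
#' when smaller than `minGapSize`.  The last contig of each chromosome
#' gets no gap.
#'
#' @param scaffolds A [ScaffoldSet-class] from [orderAndOrient()].
#' @return The [ScaffoldSet-class] with `gap_after` filled in.
#' @export
inferGaps <- function(scaffolds) {
    p <- placements(scaffolds)
    cfg <- scaffolds@config
    for (chrom in unique(p$chrom)) {
        ix <- which(p$chrom == chrom)
        ix <- ix[order(p$order_index[ix])]
        n <- length(ix)
        if (n > 1L) {
            gaps <- p$anchor_start[ix[-1L]] - p$anchor_end[ix[-n]]
            gaps[gaps <= 0] <- cfg@minGapSize
            p$gap_after[ix[-n]] <- gaps
        }
        p$gap_after[ix[n]] <- NA_real_
    }
    methods::initialize(scaffolds, placements = p)
}

#' Build scaffold sequences
#'
#' Concatenates, per chromosome, the oriented contig sequences
#' (reverse-complementing reverse placements) interleaved with runs of
#' N of the inferred gap lengths.  The scaffold is named
#' `<chrom>_scaffold`; unplaced contigs are passed through unchanged
#' under their own names.
#'
#' @param scaffolds A [ScaffoldSet-class] with gaps inferred.
#' @param contigs A [Biostrings::DNAStringSet] holding every placed
#'   contig (and any unplaced ones to pass through).
#' @return A list with `sequences` (a `DNAStringSet`: scaffolds then
#'   unplaced contigs) and `scaffolds` (the input [ScaffoldSet-class]).
#' @export
buildScaffolds <- function(scaffolds, contigs) {
    p <- placements(scaffolds)
    missing <- setdiff(p$query_name, names(contigs))
    if (length(missing))
        stop("no sequence for placed contig '", missing[1L], "'")
    out <- character(); nms <- character()
    for (chrom in sort(unique(p$chrom))) {
        pc <- p[p$chrom == chrom, , drop = FALSE]
        pc <- pc[order(pc$order_index), , drop = FALSE]
        parts <- character(0)
        for (i in seq_len(nrow(pc))) {
            s <- contigs[[pc$query_name[i]]]
            if (pc$orientation[i] == "-")
                s <- Biostrings::reverseComplement(s)
            parts <- c(parts, as.character(s))
            if (i < nrow(pc))
                parts <- c(parts, strrep("N", pc$gap_after[i]))
        }
        out <- c(out, paste(parts, collapse = ""))
        nms <- c(nms, paste0(chrom, "_scaffold"))
    }
    passthrough <- intersect(unplaced(scaffolds), names(contigs))
    for (q in passthrough) {
        out <- c(out, as.character(contigs[[q]]))
        nms <- c(nms, q)
    }
    seqs <- Biostrings::DNAStringSet(out)
    names(seqs) <- nms
    list(sequences = seqs, scaffolds = scaffolds)
}

#' Reference-guided scaffolding in one call
#'
#' Runs [assignContigs()], [orderAndOrient()], [inferGaps()] and
#' (when contig sequences are supplied) [buildScaffolds()].
#'
#' @param x A [BlockSet-class] of contig-to-reference alignments.
#' @param contigs Optional `DNAStringSet` of contig sequences.
#' @param config An [EvalConfig-class].
#' @return A [ScaffoldSet-class], or (with sequences) the list of
#'   [buildScaffolds()].
#' @export
scaffoldAssembly <- function(x, contigs = NULL, config = evalConfig()) {
    sc <- inferGaps(orderAndOrient(assignContigs(x, config), x, config))
    if (is.null(contigs)) sc else buildScaffolds(sc, contigs)
}
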