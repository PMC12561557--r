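#' Read a FASTA file of contigs or chromosomes
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims
#' headers to their first whitespace-delimited token and enforces the
#' toolkit's expectations (at least one record, unique names).  All
#' residue characters, including N, count toward sequence length.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] named by header token.
#' @export
readFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L)
        stop("no records in FASTA file '", path, "'")
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    dup <- names(seqs)[duplicated(names(seqs))]
    if (length(dup))
        stop("duplicate FASTA header token(s): ",
             paste(unique(dup), collapse = ", "))
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path, width = width)
    invisible(path)
}

#' Extract named sequence lengths
#'
#' Accepts a `DNAStringSet` or an already-named numeric vector, so
#' every downstream function can take either full sequences or a
#' name/length table.
#'
#' @param x A `DNAStringSet` or named numeric vector.
#' @return Named numeric vector of lengths in bases.
#' @export
seqLens <- function(x) {
    if (is(x, "XStringSet")) {
        out <- as.numeric(Biostrings::width(x))
        names(out) <- names(x)
    } else if (is.numeric(x)) {
        out <- as.numeric(x)
        names(out) <- names(x)
    } else {
        stop("cannot extract sequence lengths from class ", class(x)[1L])
    }
    if (is.null(names(out)) || anyDuplicated(names(out)))
        stop("sequence lengths must have unique names")
    out
}

#' Read reference chromosome lengths
#'
#' Reads either a FASTA file or a two-column name/length TSV
#' (no header), auto-detected from the first character.
#'
#' @param path Path to FASTA or TSV.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromLengths <- function(path) {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L)
        stop("no records in '", path, "'")
    if (startsWith(first, ">"))
        return(seqLens(readFasta(path)))
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("length table must have two columns: name, length")
    setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read alignment blocks from a PAF file
#'
#' Standard minimap2-style PAF: 12+ tab-separated columns
#' (qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
#' nmatch, alnlen, mapq, ...).  Coordinates are already 0-based
#' half-open; block identity is computed as
#' `100 * nmatch / alnlen` (no CIGAR parsing).  Records with zero
#' alignment length are skipped with a warning.
#'
#' @param path Path to a PAF file.
#' @return A [BlockSet-class].
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        stop("no records in PAF file '", path, "'")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 12L)
    if (length(short))
        stop("PAF line ", short[1L], " has fewer than 12 columns")
    num <- function(i, col) {
        v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
        if (anyNA(v))
            stop("non-numeric ", col, " at PAF line ", which(is.na(v))[1L])
        v
    }
    qname  <- vapply(fields, `[[`, "", 1L)
    qstart <- num(3L, "query start"); qend <- num(4L, "query end")
    strand <- vapply(fields, `[[`, "", 5L)
    tname  <- vapply(fields, `[[`, "", 6L)
    tstart <- num(8L, "target start"); tend <- num(9L, "target end")
    nmatch <- num(10L, "match count"); alnlen <- num(11L, "alignment length")
    keep <- alnlen > 0
    if (!all(keep))
        warning(sum(!keep), " PAF record(s) with zero alignment length ",
                "skipped")
    BlockSet(data.frame(
        ref_name = tname[keep], ref_start = tstart[keep],
        ref_end = tend[keep], query_name = qname[keep],
        query_start = qstart[keep], query_end = qend[keep],
        orientation = ifelse(strand[keep] == "+", "+", "-"),
        identity = 100 * nmatch[keep] / alnlen[keep],
        stringsAsFactors = FALSE))
}

.BLOCK_TSV_COLUMNS <- c("ref_name", "ref_start", "ref_end", "query_name",
                        "query_start", "query_end", "orientation",
                        "identity")

#' Read alignment blocks from the canonical block TSV
#'
#' The toolkit's tabular block dialect: a header row with columns
#' `ref_name`, `ref_start`, `ref_end`, `query_name`, `query_start`,
#' `query_end`, `orientation`, `identity`; coordinates 1-based
#' inclusive on disk.  A row whose start exceeds its end (on either
#' side) is the minus-strand convention of QUAST-style tables: it is
#' normalised to ascending coordinates with orientation set to
#' reverse.
#'
#' @param path Path to the TSV.
#' @return A [BlockSet-class] (internal 0-based half-open coordinates).
#' @export
readBlockTsv <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(.BLOCK_TSV_COLUMNS, names(tab))
    if (length(missing))
        stop("block TSV is missing column(s): ",
             paste(missing, collapse = ", "))
    revRef <- tab$ref_start > tab$ref_end
    revQry <- tab$query_start > tab$query_end
    orient <- ifelse(revRef | revQry, "-", as.character(tab$orientation))
    toHalfOpen <- function(a, b) {
        lo <- pmin(a, b); hi <- pmax(a, b)
        list(start = lo - 1, end = hi)
    }
    r <- toHalfOpen(as.numeric(tab$ref_start), as.numeric(tab$ref_end))
    q <- toHalfOpen(as.numeric(tab$query_start), as.numeric(tab$query_end))
    out <- data.frame(
        ref_name = as.character(tab$ref_name), ref_start = r$start,
        ref_end = r$end, query_name = as.character(tab$query_name),
        query_start = q$start, query_end = q$end, orientation = orient,
        identity = as.numeric(tab$identity), stringsAsFactors = FALSE)
    if (!is.null(tab$block_id))
        out$block_id <- as.character(tab$block_id)
    BlockSet(out)
}

#' Write alignment blocks to the canonical block TSV
#'
#' Inverse of [readBlockTsv()]: coordinates become 1-based inclusive;
#' reverse-orientation blocks are written with descending query
#' coordinates (the minus-strand convention), ascending reference
#' coordinates, and orientation "-".
#'
#' @param x A [BlockSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBlockTsv <- function(x, path) {
    b <- blocks(x)
    rev <- b$orientation == "-"
    out <- data.frame(
        ref_name = b$ref_name,
        ref_start = fmtBases(b$ref_start + 1),
        ref_end = fmtBases(b$ref_end),
        query_name = b$query_name,
        query_start = fmtBases(ifelse(rev, b$query_end, b$query_start + 1)),
        query_end = fmtBases(ifelse(rev, b$query_start + 1, b$query_end)),
        orientation = b$orientation,
        identity = b$identity,
        block_id = b$block_id,
        stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## Integer-valued base coordinates without scientific notation.
fmtBases <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Filter sequences by minimum length
#'
#' Retains exactly the records with length greater than or equal to
#' `minLen` (the boundary is inclusive), preserving input order.  This
#' is the evaluation floor applied to contigs before statistics and
#' scaffolding, and the read-length filter applied before assembly.
#'
#' @param seqs A `DNAStringSet` or named numeric length vector.
#' @param minLen Minimum length in bases (>= 0).
#' @return Object of the same type as `seqs`, possibly empty.
#' @export
#' @examples
#' filterByLength(c(a = 2999, b = 3000), 3000)
filterByLength <- function(seqs, minLen) {
    stopifnot(length(minLen) == 1L, minLen >= 0)
    seqs[seqLens(seqs) >= minLen]
}

#' Write a ScaffoldSet as AGP v2.1
#'
#' One AGP object per chromosome (named `<chrom>_scaffold`), with a
#' `W` line per placed contig and an `N` line (gap_type "scaffold",
#' linkage "yes") per inferred inter-contig gap.  Object and component
#' coordinates are 1-based inclusive and contiguous from 1.
#'
#' @param scaffolds A [ScaffoldSet-class].
#' @param contigLengths Contig sequences or named length vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAgp <- function(scaffolds, contigLengths, path) {
    lens <- seqLens(contigLengths)
    p <- placements(scaffolds)
    lines <- c("##agp-version\t2.1")
    for (chrom in sort(unique(p$chrom))) {
        pc <- p[p$chrom == chrom, , drop = FALSE]
        pc <- pc[order(pc$order_index), , drop = FALSE]
        obj <- paste0(chrom, "_scaffold")
        pos <- 0; part <- 0L
        for (i in seq_len(nrow(pc))) {
            qn <- pc$query_name[i]
            if (!qn %in% names(lens))
                stop("no length for placed contig '", qn, "'")
            clen <- lens[[qn]]
            if (clen < 1)
                stop("zero-length component '", qn, "'")
            part <- part + 1L
            lines <- c(lines, paste(obj, fmtBases(pos + 1),
                                    fmtBases(pos + clen), part, "W", qn,
                                    1, fmtBases(clen), pc$orientation[i],
                                    sep = "\t"))
            pos <- pos + clen
            gap <- pc$gap_after[i]
            if (i < nrow(pc) && !is.na(gap) && gap > 0) {
                part <- part + 1L
                lines <- c(lines, paste(obj, fmtBases(pos + 1),
                                        fmtBases(pos + gap), part, "N",
                                        fmtBases(gap), "scaffold", "yes",
                                        "align_genus", sep = "\t"))
                pos <- pos + gap
            }
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Parse an AGP file
#'
#' Inverse of [writeAgp()] for round-trip checking and downstream use.
#'
#' @param path Path to an AGP v2.1 file.
#' @return A data.frame with columns `object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, and for `W` lines
#'   `component_id`, `component_beg`, `component_end`, `orientation`;
#'   for `N` lines `gap_length`, `gap_type`, `linkage`.
#' @export
readAgp <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
        stop("no component lines in AGP file '", path, "'")
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9L))
        stop("AGP lines must have 9 columns")
    g <- function(i) vapply(f, `[[`, "", i)
    type <- g(5L)
    isW <- type == "W"
    numWhere <- function(v, keep) {
        out <- rep(NA_real_, length(v))
        out[keep] <- as.numeric(v[keep])
        out
    }
    chrWhere <- function(v, keep) {
        out <- rep(NA_character_, length(v))
        out[keep] <- v[keep]
        out
    }
    data.frame(
        object = g(1L), object_beg = as.numeric(g(2L)),
        object_end = as.numeric(g(3L)), part_number = as.integer(g(4L)),
        component_type = type,
        component_id = chrWhere(g(6L), isW),
        component_beg = numWhere(g(7L), isW),
        component_end = numWhere(g(8L), isW),
        orientation = chrWhere(g(9L), isW),
        gap_length = numWhere(g(6L), !isW),
        gap_type = chrWhere(g(7L), !isW),
        linkage = chrWhere(g(8L), !isW),
        stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED3+
#'
#' Intervals are written with the 0-based half-open convention BED
#' uses, which matches the toolkit's internal coordinates directly.
#'
#' @param intervals data.frame whose first three columns are chrom,
#'   start, end (0-based half-open); extra columns are appended.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
    df <- as.data.frame(intervals)
    if (ncol(df) < 3L)
        stop("BED output needs at least chrom, start, end")
    df[[2L]] <- fmtBases(df[[2L]])
    df[[3L]] <- fmtBases(df[[3L]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
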