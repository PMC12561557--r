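#' Assembly contiguity statistics (Nx / Lx)
#'
#' Computes total length, contig count, longest contig and the Nx/Lx
#' family for the requested x values.  Lengths are sorted in
#' descending order; Nx is the length of the first contig at which the
#' cumulative sum reaches at least x% of the total, and Lx is that
#' contig's 1-based rank.  The threshold uses \eqn{\ge} (the dominant
#' convention); equal lengths are interchangeable and do not affect
#' the statistics.
#'
#' @param lengths Numeric vector of sequence lengths (all >= 1), or a
#'   `DNAStringSet`.
#' @param xValues Percentages in (0, 100] at which to evaluate Nx/Lx.
#' @param nGaps Number of internal gaps (see [countScaffoldGaps()]);
#'   0 for gapless contig sets.
#' @return An [AssemblyStats-class] object.
#' @export
#' @examples
#' st <- contiguityStats(c(80, 70, 50, 40, 30, 20, 10))
#' nxValues(st)  # N50 = 70, N75 = 40, N90 = 30
contiguityStats <- function(lengths, xValues = c(50, 75, 90), nGaps = 0L) {
    if (is(lengths, "XStringSet"))
        lengths <- as.numeric(Biostrings::width(lengths))
    lengths <- as.numeric(lengths)
    if (length(lengths) == 0L)
        stop("no contigs")
    stopifnot(all(lengths >= 1), all(xValues > 0 & xValues <= 100))
    sorted <- sort(lengths, decreasing = TRUE)
    csum <- cumsum(sorted)
    total <- csum[length(csum)]
    nx <- numeric(length(xValues))
    lx <- integer(length(xValues))
    for (i in seq_along(xValues)) {
        idx <- which(csum >= xValues[i] / 100 * total)[1L]
        nx[i] <- sorted[idx]
        lx[i] <- idx
    }
    names(nx) <- names(lx) <- as.character(xValues)
    new("AssemblyStats", totalLength = total,
        nContigs = length(lengths), longest = sorted[1L],
        nx = nx, lx = lx, nGaps = as.integer(nGaps))
}

#' Count scaffold gaps
#'
#' Returns the total number of maximal runs of `N` (case-insensitive)
#' across all sequences — the "number of gaps" statistic of a
#' scaffolded assembly.
#'
#' @param seqs A `DNAStringSet` (actual sequences are required; a
#'   length-only record cannot be scanned).
#' @return Integer gap count.
#' @export
#' @examples
#' countScaffoldGaps(Biostrings::DNAStringSet(c(s = "ACGTNNNNACGT")))
countScaffoldGaps <- function(seqs) {
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (!is(seqs, "XStringSet"))
        stop("countScaffoldGaps needs sequences, got ", class(seqs)[1L])
    total <- 0L
    for (i in seq_along(seqs)) {
        runs <- Biostrings::masks(Biostrings::maskMotif(seqs[[i]], "N"))
        total <- total + if (is.null(runs)) 0L else length(runs[[1L]])
    }
    total
}

#' One-row assembly statistics table
#'
#' Flattens an [AssemblyStats-class] into the column layout of an
#' assembly summary table (total length, longest, Nx/Lx, counts).
#'
#' @param stats An [AssemblyStats-class].
#' @return A one-row data.frame.
#' @export
assemblyStatsTable <- function(stats) {
    row <- data.frame(assembly_length = stats@totalLength,
                      longest_contig = stats@longest,
                      stringsAsFactors = FALSE)
    for (x in names(stats@nx))
        row[[paste0("N", x)]] <- stats@nx[[x]]
    for (x in names(stats@lx))
        row[[paste0("L", x)]] <- stats@lx[[x]]
    row$n_contigs <- stats@nContigs
    row$n_gaps <- stats@nGaps
    row
}
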