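#' @import methods
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

## Orientation is encoded strand-style throughout: "+" = forward, "-" = reverse.
.ORIENTATIONS <- c("+", "-")

.BLOCK_COLUMNS <- c("ref_name", "ref_start", "ref_end",
                    "query_name", "query_start", "query_end",
                    "orientation", "identity", "block_id")

#' BlockSet: a collection of contig-to-reference alignment blocks
#'
#' The atom of the toolkit.  Each row describes one contiguous aligned
#' segment between a contig (query) and a reference chromosome, with
#' coordinates on both sides, an orientation and a percent identity.
#' Coordinates are stored 0-based half-open with `start < end` on both
#' the reference and the query; the `orientation` column ("+"/"-")
#' carries strand.
#'
#' @slot blocks A `data.frame` with columns `ref_name`, `ref_start`,
#'   `ref_end`, `query_name`, `query_start`, `query_end`,
#'   `orientation`, `identity`, `block_id`.
#' @export
setClass("BlockSet", representation(blocks = "data.frame"))

setValidity("BlockSet", function(object) {
    b <- object@blocks
    missing <- setdiff(.BLOCK_COLUMNS, names(b))
    if (length(missing))
        return(paste("missing block columns:", paste(missing, collapse = ", ")))
    if (nrow(b) == 0L)
        return(TRUE)
    if (any(b$ref_start >= b$ref_end))
        return("ref_start must be < ref_end for every block")
    if (any(b$query_start >= b$query_end))
        return("query_start must be < query_end for every block")
    if (any(b$ref_start < 0) || any(b$query_start < 0))
        return("coordinates must be non-negative")
    if (!all(b$orientation %in% .ORIENTATIONS))
        return("orientation must be '+' or '-'")
    if (any(b$identity < 0 | b$identity > 100))
        return("identity must lie in [0, 100]")
    if (anyDuplicated(b$block_id))
        return("block_id values must be unique")
    TRUE
})

#' Construct a BlockSet
#'
#' @param blocks A data.frame of alignment blocks.  `block_id` is
#'   generated when absent; `identity` defaults to 100.
#' @return A [BlockSet-class] object.
#' @export
#' @examples
#' bs <- BlockSet(data.frame(ref_name = "chr1", ref_start = 0, ref_end = 100,
#'                           query_name = "ctg1", query_start = 0,
#'                           query_end = 100, orientation = "+"))
#' nBlocks(bs)
BlockSet <- function(blocks = data.frame()) {
    b <- as.data.frame(blocks, stringsAsFactors = FALSE)
    if (nrow(b)) {
        if (is.null(b$identity))
            b$identity <- 100
        if (is.null(b$block_id))
            b$block_id <- sprintf("b%06d", seq_len(nrow(b)))
        for (col in c("ref_start", "ref_end", "query_start", "query_end",
                      "identity"))
            b[[col]] <- as.numeric(b[[col]])
        for (col in c("ref_name", "query_name", "orientation", "block_id"))
            b[[col]] <- as.character(b[[col]])
        b <- b[.BLOCK_COLUMNS]
        rownames(b) <- NULL
    } else {
        b <- data.frame(ref_name = character(), ref_start = numeric(),
                        ref_end = numeric(), query_name = character(),
                        query_start = numeric(), query_end = numeric(),
                        orientation = character(), identity = numeric(),
                        block_id = character(), stringsAsFactors = FALSE)
    }
    new("BlockSet", blocks = b)
}

#' Evaluation and scaffolding configuration
#'
#' Holds every tunable threshold of the toolkit.  Lengths are in bases.
#'
#' @slot minContig Contigs shorter than this are excluded from
#'   statistics and scaffolding (default 3000).
#' @slot minReadLen Read-length floor for the read-filter utility
#'   (default 500).
#' @slot minUncovered Minimum length for a reported uncovered reference
#'   stretch (default 5000).
#' @slot colinearGapTol Maximum reference gap, in bases, across which a
#'   colinear run may be extended (default 1e5).
#' @slot hotspotWindow Window size for fragmentation-hotspot scanning
#'   (default 1e6).
#' @slot hotspotMinInterruptions Minimum number of block boundaries in a
#'   window for it to be flagged as a hotspot (default 10).
#' @slot minGapSize Spacer inserted between abutting/overlapping
#'   scaffold components (default 100).
#' @slot minAssignFraction Minimum fraction of a contig's aligned
#'   length that must fall on one chromosome for placement (default 0.6).
#' @slot seed Integer seed for any randomised step.
#' @export
setClass("EvalConfig",
    representation(minContig = "numeric", minReadLen = "numeric",
                   minUncovered = "numeric", colinearGapTol = "numeric",
                   hotspotWindow = "numeric",
                   hotspotMinInterruptions = "numeric",
                   minGapSize = "numeric", minAssignFraction = "numeric",
                   seed = "integer"))

setValidity("EvalConfig", function(object) {
    lens <- c(minContig = object@minContig, minReadLen = object@minReadLen,
              minUncovered = object@minUncovered,
              colinearGapTol = object@colinearGapTol,
              hotspotWindow = object@hotspotWindow,
              hotspotMinInterruptions = object@hotspotMinInterruptions,
              minGapSize = object@minGapSize)
    if (any(lens <= 0))
        return("all length/count thresholds must be positive")
    f <- object@minAssignFraction
    if (length(f) != 1L || f <= 0 || f > 1)
        return("minAssignFraction must lie in (0, 1]")
    TRUE
})

#' @rdname EvalConfig-class
#' @param minContig,minReadLen,minUncovered,colinearGapTol Length
#'   thresholds in bases (see slots).
#' @param hotspotWindow,hotspotMinInterruptions Hotspot scan parameters.
#' @param minGapSize,minAssignFraction Scaffolding parameters.
#' @param seed Integer seed.
#' @return An `EvalConfig` object.
#' @export
evalConfig <- function(minContig = 3000, minReadLen = 500,
                       minUncovered = 5000, colinearGapTol = 1e5,
                       hotspotWindow = 1e6, hotspotMinInterruptions = 10,
                       minGapSize = 100, minAssignFraction = 0.6,
                       seed = 1L) {
    new("EvalConfig", minContig = minContig, minReadLen = minReadLen,
        minUncovered = minUncovered, colinearGapTol = colinearGapTol,
        hotspotWindow = hotspotWindow,
        hotspotMinInterruptions = hotspotMinInterruptions,
        minGapSize = minGapSize, minAssignFraction = minAssignFraction,
        seed = as.integer(seed))
}

#' Whole-assembly contiguity statistics
#'
#' Totals, longest contig, Nx/Lx values and (for scaffolded
#' assemblies) the number of internal gaps.
#'
#' @slot totalLength Total assembled bases.
#' @slot nContigs Number of sequences.
#' @slot longest Length of the longest sequence.
#' @slot nx Named numeric: Nx value per requested x (e.g. "50").
#' @slot lx Named integer: Lx value per requested x.
#' @slot nGaps Number of N-runs (0 for gapless contig sets).
#' @export
setClass("AssemblyStats",
    representation(totalLength = "numeric", nContigs = "integer",
                   longest = "numeric", nx = "numeric", lx = "integer",
                   nGaps = "integer"))

setValidity("AssemblyStats", function(object) {
    if (length(object@nx) != length(object@lx))
        return("nx and lx must be parallel")
    if (!identical(names(object@nx), names(object@lx)))
        return("nx and lx must share names")
    if (any(object@lx > object@nContigs))
        return("Lx cannot exceed the number of contigs")
    if (length(object@nx) && any(object@nx > object@longest))
        return("Nx cannot exceed the longest contig")
    if (object@longest > object@totalLength)
        return("longest contig cannot exceed total length")
    TRUE
})

#' Ordered, oriented contig placements per chromosome
#'
#' The scaffolding result: one row of `placements` per placed contig,
#' with its chromosome, 0-based rank, orientation, reference anchor
#' interval (0-based half-open), assignment confidence and the gap (in
#' N bases) inserted after it; contigs failing the assignment filter
#' are listed in `unplaced`.
#'
#' @slot placements data.frame with columns `query_name`, `chrom`,
#'   `order_index`, `orientation`, `anchor_start`, `anchor_end`,
#'   `assign_fraction`, `gap_after` (NA for the last contig of each
#'   chromosome).
#' @slot unplaced Character vector of unplaced contig names.
#' @slot config The [EvalConfig-class] snapshot used to build it.
#' @export
setClass("ScaffoldSet",
    representation(placements = "data.frame", unplaced = "character",
                   config = "EvalConfig"))

setValidity("ScaffoldSet", function(object) {
    p <- object@placements
    need <- c("query_name", "chrom", "order_index", "orientation",
              "anchor_start", "anchor_end", "assign_fraction")
    missing <- setdiff(need, names(p))
    if (length(missing))
        return(paste("missing placement columns:",
                     paste(missing, collapse = ", ")))
    if (nrow(p) == 0L)
        return(TRUE)
    if (anyDuplicated(p$query_name))
        return("a contig may be placed at most once")
    if (any(p$query_name %in% object@unplaced))
        return("a contig cannot be both placed and unplaced")
    if (any(p$anchor_start >= p$anchor_end))
        return("anchor_start must be < anchor_end")
    if (any(p$assign_fraction <= 0 | p$assign_fraction > 1))
        return("assign_fraction must lie in (0, 1]")
    bad <- vapply(split(p$order_index, p$chrom),
                  function(ix) any(diff(sort(ix)) != 1L) || min(ix) != 0L,
                  logical(1))
    if (any(bad))
        return("order_index must be 0..n-1 per chromosome")
    TRUE
})

#' Ground truth emitted by the fragmented-genome simulator
#'
#' @slot trueBlocks [BlockSet-class] of the exact source interval of
#'   every simulated contig (identity 100 unless noise was added).
#' @slot trueOrder data.frame (`chrom`, `query_name`, `orientation`,
#'   `order_index`): the left-to-right fragment order per chromosome.
#' @slot trueGaps data.frame (`chrom`, `query_name`, `gap`): reference
#'   distance from the end of each fragment to the start of the next.
#' @slot trueInversions data.frame (`chrom`, `start`, `end`,
#'   `query_name`) of reverse-complemented fragments.
#' @slot trueDropped data.frame (`chrom`, `start`, `end`, `length`) of
#'   excised reference intervals.
#' @slot centromereInterval data.frame (`chrom`, `start`, `end`), 0 or
#'   1 row: the planted shattered repeat-array interval.
#' @export
setClass("SimTruth",
    representation(trueBlocks = "BlockSet", trueOrder = "data.frame",
                   trueGaps = "data.frame", trueInversions = "data.frame",
                   trueDropped = "data.frame",
                   centromereInterval = "data.frame"))

#' Simulator configuration
#'
#' Defines a synthetic reference genome and how it is fragmented into
#' contigs.  The defaults describe a toy genome whose geometry mirrors
#' what a long-read assembly of a mammalian genome looks like against
#' its reference: chromosomes covered end-to-end by a modest number of
#' long fragments, rare multi-kilobase missing stretches, occasional
#' inverted fragments, and one repeat-array region that shatters into
#' many micro-fragments.
#'
#' @slot chromLengths Named numeric: chromosome name -> length (bases).
#' @slot nFragments Integer vector (recycled over chromosomes): number
#'   of fragments each chromosome is cut into.
#' @slot droppedIntervals data.frame (`chrom`, `start`, `length`):
#'   reference intervals excised before fragmenting (0-based start).
#' @slot inversionRate Probability that a fragment is emitted
#'   reverse-complemented.
#' @slot centromere Either `NULL` or a list with `chrom`, `position`,
#'   `arrayLength`, `repeatUnitLength`, `shatterCount` describing a
#'   tandem repeat array spliced into the reference and re-cut into
#'   `shatterCount` micro-fragments.
#' @slot identityNoise Per-base substitution probability used to perturb
#'   the identity of the truth blocks.
#' @slot minFragmentLength Minimum fragment length enforced when
#'   drawing breakpoints (default 3000, the contig evaluation floor:
#'   shorter fragments would be discarded by every downstream step).
#'   Dropped-interval and centromere-shatter boundaries may still cut
#'   shorter pieces.
#' @slot seed Integer seed; all simulator randomness derives from it.
#' @export
setClass("SimConfig",
    representation(chromLengths = "numeric", nFragments = "numeric",
                   droppedIntervals = "data.frame",
                   inversionRate = "numeric", centromere = "ANY",
                   identityNoise = "numeric",
                   minFragmentLength = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (!length(object@chromLengths) || any(object@chromLengths < 1))
        return("chromLengths must be positive")
    if (is.null(names(object@chromLengths)) ||
        anyDuplicated(names(object@chromLengths)))
        return("chromLengths must have unique names")
    if (any(object@nFragments < 1))
        return("nFragments must be >= 1")
    if (object@inversionRate < 0 || object@inversionRate > 1)
        return("inversionRate must lie in [0, 1]")
    if (object@identityNoise < 0 || object@identityNoise >= 1)
        return("identityNoise must lie in [0, 1)")
    if (object@minFragmentLength < 1)
        return("minFragmentLength must be positive")
    nf <- rep_len(object@nFragments, length(object@chromLengths))
    if (any(nf * object@minFragmentLength > object@chromLengths))
        return("nFragments * minFragmentLength exceeds chromosome length")
    d <- object@droppedIntervals
    if (nrow(d)) {
        if (!all(c("chrom", "start", "length") %in% names(d)))
            return("droppedIntervals needs chrom, start, length")
        if (any(d$length < 1) || any(d$start < 0))
            return("dropped intervals must have positive length")
        for (ch in unique(d$chrom)) {
            dd <- d[d$chrom == ch, , drop = FALSE]
            dd <- dd[order(dd$start), , drop = FALSE]
            if (nrow(dd) > 1L &&
                any(dd$start[-1L] < (dd$start + dd$length)[-nrow(dd)]))
                return("dropped intervals must be disjoint per chromosome")
            if (!ch %in% names(object@chromLengths))
                return(paste("dropped interval on unknown chromosome", ch))
            if (any(dd$start + dd$length > object@chromLengths[[ch]]))
                return("dropped interval exceeds chromosome length")
        }
    }
    cen <- object@centromere
    if (!is.null(cen)) {
        need <- c("chrom", "position", "arrayLength", "repeatUnitLength",
                  "shatterCount")
        if (!is.list(cen) || !all(need %in% names(cen)))
            return(paste("centromere needs", paste(need, collapse = ", ")))
        if (!cen$chrom %in% names(object@chromLengths))
            return("centromere chromosome not in chromLengths")
        if (cen$position + cen$arrayLength >
            object@chromLengths[[cen$chrom]])
            return("centromere interval exceeds chromosome length")
    }
    TRUE
})

#' @rdname SimConfig-class
#' @param chromLengths,nFragments,droppedIntervals,inversionRate See slots.
#' @param centromere,identityNoise,minFragmentLength,seed See slots.
#' @return A `SimConfig` object.
#' @export
simConfig <- function(chromLengths = c(chrA = 2e6, chrB = 1e6, chrC = 5e5),
                      nFragments = c(30, 20, 10),
                      droppedIntervals = data.frame(chrom = character(),
                                                    start = numeric(),
                                                    length = numeric()),
                      inversionRate = 0,
                      centromere = NULL,
                      identityNoise = 0,
                      minFragmentLength = 3000,
                      seed = 1L) {
    new("SimConfig", chromLengths = chromLengths,
        nFragments = as.numeric(nFragments),
        droppedIntervals = as.data.frame(droppedIntervals),
        inversionRate = inversionRate, centromere = centromere,
        identityNoise = identityNoise,
        minFragmentLength = minFragmentLength, seed = as.integer(seed))
}
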