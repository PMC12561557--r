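#' Accessors
#'
#' Small accessor generics for the toolkit's S4 containers.
#'
#' @param x An object.
#' @return `blocks()` the block data.frame; `nBlocks()` its row count;
#'   `placements()` / `unplaced()` the placement table and the unplaced
#'   contig names of a [ScaffoldSet-class]; `trueBlocks()` /
#'   `trueOrder()` / `trueGaps()` / `trueInversions()` / `trueDropped()`
#'   the corresponding slots of a [SimTruth-class]; `nxValues()` /
#'   `lxValues()` the Nx/Lx vectors of an [AssemblyStats-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setMethod("blocks", "BlockSet", function(x) x@blocks)
#' @rdname accessors
#' @export
setMethod("blocks", "SimTruth", function(x) x@trueBlocks@blocks)

#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @rdname accessors
#' @export
setMethod("nBlocks", "BlockSet", function(x) nrow(x@blocks))

#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setMethod("placements", "ScaffoldSet", function(x) x@placements)

#' @rdname accessors
#' @export
setGeneric("unplaced", function(x) standardGeneric("unplaced"))
#' @rdname accessors
#' @export
setMethod("unplaced", "ScaffoldSet", function(x) x@unplaced)

#' @rdname accessors
#' @export
setGeneric("trueBlocks", function(x) standardGeneric("trueBlocks"))
#' @rdname accessors
#' @export
setMethod("trueBlocks", "SimTruth", function(x) x@trueBlocks)

#' @rdname accessors
#' @export
setGeneric("trueOrder", function(x) standardGeneric("trueOrder"))
#' @rdname accessors
#' @export
setMethod("trueOrder", "SimTruth", function(x) x@trueOrder)

#' @rdname accessors
#' @export
setGeneric("trueGaps", function(x) standardGeneric("trueGaps"))
#' @rdname accessors
#' @export
setMethod("trueGaps", "SimTruth", function(x) x@trueGaps)

#' @rdname accessors
#' @export
setGeneric("trueInversions", function(x) standardGeneric("trueInversions"))
#' @rdname accessors
#' @export
setMethod("trueInversions", "SimTruth", function(x) x@trueInversions)

#' @rdname accessors
#' @export
setGeneric("trueDropped", function(x) standardGeneric("trueDropped"))
#' @rdname accessors
#' @export
setMethod("trueDropped", "SimTruth", function(x) x@trueDropped)

#' @rdname accessors
#' @export
setGeneric("centromereInterval",
           function(x) standardGeneric("centromereInterval"))
#' @rdname accessors
#' @export
setMethod("centromereInterval", "SimTruth",
          function(x) x@centromereInterval)

#' @rdname accessors
#' @export
setGeneric("nxValues", function(x) standardGeneric("nxValues"))
#' @rdname accessors
#' @export
setMethod("nxValues", "AssemblyStats", function(x) x@nx)

#' @rdname accessors
#' @export
setGeneric("lxValues", function(x) standardGeneric("lxValues"))
#' @rdname accessors
#' @export
setMethod("lxValues", "AssemblyStats", function(x) x@lx)

#' @rdname accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setMethod("totalLength", "AssemblyStats", function(x) x@totalLength)

#' @rdname accessors
#' @export
setGeneric("nGaps", function(x) standardGeneric("nGaps"))
#' @rdname accessors
#' @export
setMethod("nGaps", "AssemblyStats", function(x) x@nGaps)

setMethod("show", "BlockSet", function(object) {
    b <- object@blocks
    cat("BlockSet with", nrow(b), "alignment blocks on",
        length(unique(b$ref_name)), "chromosome(s) from",
        length(unique(b$query_name)), "contig(s)\n")
    if (nrow(b)) {
        cat("  mean identity:", round(mean(b$identity), 2), "%\n")
        print(head(b, 5L))
        if (nrow(b) > 5L) cat("  ...", nrow(b) - 5L, "more rows\n")
    }
    invisible(NULL)
})

setMethod("show", "EvalConfig", function(object) {
    cat("EvalConfig:\n",
        " minContig =", object@minContig,
        " minReadLen =", object@minReadLen, "\n",
        " minUncovered =", object@minUncovered,
        " colinearGapTol =", object@colinearGapTol, "\n",
        " hotspotWindow =", object@hotspotWindow,
        " hotspotMinInterruptions =", object@hotspotMinInterruptions, "\n",
        " minGapSize =", object@minGapSize,
        " minAssignFraction =", object@minAssignFraction,
        " seed =", object@seed, "\n")
    invisible(NULL)
})

setMethod("show", "AssemblyStats", function(object) {
    cat("AssemblyStats:", object@nContigs, "contigs,",
        format(object@totalLength, big.mark = ","), "bases, longest",
        format(object@longest, big.mark = ","), "\n")
    for (x in names(object@nx))
        cat(sprintf("  N%s = %s  L%s = %d\n", x,
                    format(object@nx[[x]], big.mark = ","), x,
                    object@lx[[x]]))
    cat("  gaps:", object@nGaps, "\n")
    invisible(NULL)
})

setMethod("show", "ScaffoldSet", function(object) {
    p <- object@placements
    cat("ScaffoldSet:", nrow(p), "contigs placed on",
        length(unique(p$chrom)), "chromosome(s);",
        length(object@unplaced), "unplaced\n")
    invisible(NULL)
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nBlocks(object@trueBlocks), "truth blocks,",
        nrow(object@trueInversions), "inversions,",
        nrow(object@trueDropped), "dropped intervals\n")
    invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(object@chromLengths), "chromosomes (",
        format(sum(object@chromLengths), big.mark = ","), "bases ),",
        "seed", object@seed, "\n")
    invisible(NULL)
})
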