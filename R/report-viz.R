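## Deterministic colour cycle for contigs (palette fixed by design so
## repeated renders are identical).
.CONTIG_COLOURS <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                     "#66a61e", "#e6ab02", "#a6761d", "#666666")

## Extract the blocks of exactly one chromosome from a BlockSet or
## data.frame, sorted by reference start.
.oneChromBlocks <- function(x, chrom = NULL) {
    b <- if (is(x, "BlockSet")) blocks(x) else as.data.frame(x)
    if (!is.null(chrom))
        b <- b[b$ref_name == chrom, , drop = FALSE]
    if (nrow(b) == 0L)
        stop("nothing to draw")
    if (length(unique(b$ref_name)) > 1L)
        stop("plots are per-chromosome; pass `chrom` to select one")
    b[order(b$ref_start, b$ref_end), , drop = FALSE]
}

## Geometry for the stacked chromosome map: one horizontal level per
## contig (ordered by leftmost reference position), one rectangle per
## block, one vertical boundary marker per block edge.
.stackedMapGeometry <- function(b, chromLength) {
    leftmost <- tapply(b$ref_start, b$query_name, min)
    order <- names(sort(leftmost))
    level <- match(b$query_name, order)
    col <- .CONTIG_COLOURS[(level - 1L) %% length(.CONTIG_COLOURS) + 1L]
    list(nLevels = length(order), contigOrder = order,
         rects = data.frame(x0 = b$ref_start, x1 = b$ref_end,
                            level = level, colour = col,
                            stringsAsFactors = FALSE),
         boundaries = sort(unique(c(b$ref_start, b$ref_end))),
         xMax = max(chromLength, b$ref_end))
}

## Geometry for the dotplot: one segment per block (ascending slope
## for forward blocks, descending for reverse), circle at the start
## point and triangle at the stop point; contigs stacked cumulatively
## on the y axis in leftmost-reference order.
.dotplotGeometry <- function(b, chromLength) {
    leftmost <- tapply(b$ref_start, b$query_name, min)
    order <- names(sort(leftmost))
    extent <- tapply(b$query_end, b$query_name, max)[order]
    offset <- setNames(cumsum(c(0, extent[-length(extent)])), order)
    y0 <- offset[b$query_name] +
        ifelse(b$orientation == "+", b$query_start, b$query_end)
    y1 <- offset[b$query_name] +
        ifelse(b$orientation == "+", b$query_end, b$query_start)
    level <- match(b$query_name, order)
    col <- .CONTIG_COLOURS[(level - 1L) %% length(.CONTIG_COLOURS) + 1L]
    list(segments = data.frame(x0 = b$ref_start, x1 = b$ref_end,
                               y0 = as.numeric(y0), y1 = as.numeric(y1),
                               colour = col, stringsAsFactors = FALSE),
         yMax = sum(extent), xMax = max(chromLength, b$ref_end))
}

.svgHeader <- function(width, height)
    c('<?xml version="1.0" encoding="UTF-8"?>',
      sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                     'width="%d" height="%d" viewBox="0 0 %d %d">'),
              width, height, width, height))

#' Render a stacked chromosome map
#'
#' One horizontal level per contig (ordered by leftmost reference
#' position) with one coloured rectangle per alignment block,
#' positioned by reference coordinates, and a vertical black marker at
#' every block boundary.  SVG is the canonical output (every drawn
#' element is a countable node); PNG is a rasterised convenience.
#'
#' @param x A [BlockSet-class] (or block data.frame) for one
#'   chromosome, or a multi-chromosome set together with `chrom`.
#' @param path Output file path.
#' @param chrom Chromosome to draw when `x` spans several.
#' @param chromLength Reference length for the x axis (defaults to the
#'   rightmost block end).
#' @param format "svg" or "png".
#' @param width,height Image dimensions in pixels.
#' @return `path`, invisibly.
#' @export
renderStackedMap <- function(x, path, chrom = NULL, chromLength = NULL,
                             format = c("svg", "png"), width = 1000L,
                             height = NULL) {
    format <- match.arg(format)
    b <- .oneChromBlocks(x, chrom)
    geo <- .stackedMapGeometry(b, chromLength %||% max(b$ref_end))
    lh <- 16L
    height <- height %||% as.integer(geo$nLevels * lh + 20L)
    sx <- (width - 20) / geo$xMax
    px <- function(v) 10 + v * sx
    py <- function(level) 10 + (level - 1L) * lh
    if (format == "png") {
        grDevices::png(path, width = width, height = height)
        on.exit(grDevices::dev.off())
        graphics::par(mar = c(0, 0, 0, 0))
        graphics::plot(NA, xlim = c(0, width), ylim = c(height, 0),
                       axes = FALSE, xlab = "", ylab = "")
        graphics::rect(px(geo$rects$x0), py(geo$rects$level),
                       px(geo$rects$x1), py(geo$rects$level) + lh - 4,
                       col = geo$rects$colour, border = NA)
        graphics::segments(px(geo$boundaries), 0, px(geo$boundaries),
                           height, col = "black")
        return(invisible(path))
    }
    out <- .svgHeader(width, height)
    out <- c(out, sprintf(
        paste0('<rect class="block-rect" x="%.2f" y="%.2f" ',
               'width="%.2f" height="%d" fill="%s"/>'),
        px(geo$rects$x0), py(geo$rects$level),
        (geo$rects$x1 - geo$rects$x0) * sx, lh - 4L, geo$rects$colour))
    out <- c(out, sprintf(
        paste0('<line class="boundary" x1="%.2f" y1="0" x2="%.2f" ',
               'y2="%d" stroke="black" stroke-width="0.5"/>'),
        px(geo$boundaries), px(geo$boundaries), height))
    out <- c(out, "</svg>")
    writeLines(out, path)
    invisible(path)
}

#' Render a dotplot of alignment blocks
#'
#' One line segment per block from (ref_start, query offset start) to
#' (ref_end, query offset end) — ascending for forward blocks,
#' descending (opposite slope) for reverse blocks — with a circle
#' marker at the segment start and a triangle at the stop.  Contigs
#' are stacked cumulatively on the vertical axis in leftmost-reference
#' order, so colinear assemblies appear as long linear stretches of
#' same-slope segments.
#'
#' @inheritParams renderStackedMap
#' @return `path`, invisibly.
#' @export
renderDotplot <- function(x, path, chrom = NULL, chromLength = NULL,
                          format = c("svg", "png"), width = 1000L,
                          height = 600L) {
    format <- match.arg(format)
    b <- .oneChromBlocks(x, chrom)
    geo <- .dotplotGeometry(b, chromLength %||% max(b$ref_end))
    sx <- (width - 20) / geo$xMax
    sy <- (height - 20) / max(geo$yMax, 1)
    px <- function(v) 10 + v * sx
    py <- function(v) height - 10 - v * sy
    s <- geo$segments
    if (format == "png") {
        grDevices::png(path, width = width, height = height)
        on.exit(grDevices::dev.off())
        graphics::par(mar = c(0, 0, 0, 0))
        graphics::plot(NA, xlim = c(0, width), ylim = c(height, 0),
                       axes = FALSE, xlab = "", ylab = "")
        graphics::segments(px(s$x0), py(s$y0), px(s$x1), py(s$y1),
                           col = s$colour)
        graphics::points(px(s$x0), py(s$y0), pch = 19, col = s$colour)
        graphics::points(px(s$x1), py(s$y1), pch = 17, col = s$colour)
        return(invisible(path))
    }
    out <- .svgHeader(width, height)
    out <- c(out, sprintf(
        paste0('<line class="block-seg" x1="%.2f" y1="%.2f" x2="%.2f" ',
               'y2="%.2f" stroke="%s" stroke-width="1.5"/>'),
        px(s$x0), py(s$y0), px(s$x1), py(s$y1), s$colour))
    out <- c(out, sprintf(
        '<circle class="start-marker" cx="%.2f" cy="%.2f" r="3" fill="%s"/>',
        px(s$x0), py(s$y0), s$colour))
    tri <- function(cx, cy, col)
        sprintf(paste0('<polygon class="end-marker" points="%.2f,%.2f ',
                       '%.2f,%.2f %.2f,%.2f" fill="%s"/>'),
                cx, cy - 4, cx - 3.5, cy + 3, cx + 3.5, cy + 3, col)
    out <- c(out, tri(px(s$x1), py(s$y1), s$colour))
    out <- c(out, "</svg>")
    writeLines(out, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Percentages are printed with one decimal; round() is half-even,
## matching the documented rounding rule.
.fmtPct <- function(x) ifelse(is.na(x), "NA",
                              formatC(round(x, 1), format = "f",
                                      digits = 1))

#' Format a per-chromosome report for printing
#'
#' Applies the published table layout: a leading chromosome column,
#' then Start, End, Coverage, n Contigs, L90, L50, Identity, n Blocks,
#' with percentages printed to one decimal.
#'
#' @param reports Output of [chromosomeReport()].
#' @return A data.frame of formatted character/numeric columns.
#' @export
formatChromosomeReport <- function(reports) {
    fmtPos <- function(x) ifelse(is.na(x), "NA", fmtBases(x))
    data.frame(chromosome = reports$chrom,
               Start = fmtPos(reports$align_start),
               End = fmtPos(reports$align_end),
               Coverage = .fmtPct(reports$coverage_pct),
               `n Contigs` = reports$n_contigs,
               L90 = reports$l90, L50 = reports$l50,
               Identity = .fmtPct(reports$identity_pct),
               `n Blocks` = reports$n_blocks,
               check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write the tabular reports
#'
#' Writes the assembly statistics TSV, the per-chromosome report TSV
#' (published column layout, percentages to one decimal) and, when
#' supplied, the block-annotation TSV.
#'
#' @param assemblyStats An [AssemblyStats-class], or NULL to skip.
#' @param chromReports Output of [chromosomeReport()], or NULL.
#' @param annotations Output of [annotateBlocks()], or NULL.
#' @param prefix Path prefix; files get `_assembly.tsv`,
#'   `_chromosomes.tsv`, `_blocks.tsv` suffixes.
#' @return Character vector of the files written, invisibly.
#' @export
writeReports <- function(assemblyStats = NULL, chromReports = NULL,
                         annotations = NULL, prefix = "report") {
    written <- character()
    tsv <- function(df, path) {
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        written <<- c(written, path)
    }
    if (!is.null(assemblyStats))
        tsv(assemblyStatsTable(assemblyStats),
            paste0(prefix, "_assembly.tsv"))
    if (!is.null(chromReports))
        tsv(formatChromosomeReport(chromReports),
            paste0(prefix, "_chromosomes.tsv"))
    if (!is.null(annotations))
        tsv(annotations, paste0(prefix, "_blocks.tsv"))
    invisible(written)
}
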