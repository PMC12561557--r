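## All simulator randomness derives from one documented scheme:
## simulateReference() seeds the stream with `seed`, fragmentGenome()
## with `seed + 1`, and addIdentityNoise() with the seed it is given
## (simulateAssembly() passes `seed + 2`), so the three stages are
## independently reproducible.

.randomSeq <- function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")

#' Simulate a reference genome
#'
#' Generates uniform-random A/C/G/T chromosomes of the configured
#' lengths.  When a centromere is configured, a tandem repeat array
#' (one random unit of `repeatUnitLength` bases repeated to
#' `arrayLength`) is spliced in at the stated position, emulating the
#' repeat-rich region that resists assembly.  Deterministic given the
#' seed.
#'
#' @param config A [SimConfig-class].
#' @return A [Biostrings::DNAStringSet] of reference chromosomes.
#' @export
simulateReference <- function(config) {
    set.seed(config@seed)
    lens <- config@chromLengths
    seqs <- vapply(lens, .randomSeq, "")
    cen <- config@centromere
    if (!is.null(cen)) {
        unit <- .randomSeq(cen$repeatUnitLength)
        array <- strtrim(strrep(unit, ceiling(cen$arrayLength /
                                              cen$repeatUnitLength)),
                         cen$arrayLength)
        s <- seqs[[cen$chrom]]
        if (cen$position + cen$arrayLength > nchar(s))
            stop("centromere interval exceeds chromosome length")
        substr(s, cen$position + 1, cen$position + cen$arrayLength) <- array
        seqs[[cen$chrom]] <- s
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(lens)
    out
}

#' Fragment a reference genome into contigs with known truth
#'
#' Cuts each chromosome at randomly drawn breakpoints into the
#' configured number of fragments, excises the configured dropped
#' intervals (recorded as truth), re-cuts the centromere interval (if
#' any) into `shatterCount` micro-fragments, and reverse-complements
#' each surviving fragment with probability `inversionRate`
#' (recorded).  Every surviving fragment becomes a contig whose exact
#' source interval, orientation and identity (100) are emitted as a
#' truth alignment block.  Deterministic given the seed.
#'
#' @param reference A `DNAStringSet` from [simulateReference()] (or a
#'   user FASTA read with [readFasta()]).
#' @param config The [SimConfig-class] used to build the reference.
#' @return A list with `contigs` (a `DNAStringSet`) and `truth`
#'   (a [SimTruth-class]).
#' @export
fragmentGenome <- function(reference, config) {
    set.seed(config@seed + 1L)
    lens <- seqLens(reference)
    nFrag <- rep_len(config@nFragments, length(lens))
    cen <- config@centromere
    blockRows <- list(); orderRows <- list(); gapRows <- list()
    invRows <- list(); dropRows <- list()
    contigSeqs <- character(); contigNames <- character()
    for (ci in seq_along(lens)) {
        ch <- names(lens)[ci]; len <- lens[[ci]]
        d <- config@droppedIntervals
        d <- d[d$chrom == ch, , drop = FALSE]
        d <- d[order(d$start), , drop = FALSE]
        dropStart <- as.numeric(d$start)
        dropEnd <- dropStart + as.numeric(d$length)
        cuts <- c(0, len, dropStart, dropEnd)
        k <- nFrag[ci] - 1L
        if (k > 0L) {
            ## draw cuts with a minimum spacing m: choose k distinct
            ## positions in the "slack" 1..(len - n*m) and shift the
            ## i-th by i*m, which guarantees every fragment >= m
            m <- config@minFragmentLength
            slack <- len - nFrag[ci] * m
            if (slack < k)
                stop("cannot cut ", len, " bases into ", nFrag[ci],
                     " fragments of >= ", m, " bases")
            cuts <- c(cuts, sort(sample(slack, k)) + seq_len(k) * m)
        }
        if (!is.null(cen) && cen$chrom == ch) {
            cs <- cen$position; ce <- cen$position + cen$arrayLength
            micro <- if (cen$shatterCount > 1L)
                cs + sort(sample(cen$arrayLength - 1L,
                                 cen$shatterCount - 1L))
            else numeric()
            cuts <- c(cuts, cs, ce, micro)
        }
        cuts <- sort(unique(cuts))
        segStart <- cuts[-length(cuts)]
        segEnd <- cuts[-1L]
        inDrop <- rep(FALSE, length(segStart))
        for (j in seq_along(dropStart))
            inDrop <- inDrop | (segStart >= dropStart[j] &
                                segEnd <= dropEnd[j])
        segStart <- segStart[!inDrop]; segEnd <- segEnd[!inDrop]
        n <- length(segStart)
        rev <- runif(n) < config@inversionRate
        nms <- sprintf("%s_frag%03d", ch, seq_len(n))
        chSeq <- reference[[ch]]
        for (i in seq_len(n)) {
            s <- Biostrings::subseq(chSeq, segStart[i] + 1, segEnd[i])
            if (rev[i]) s <- Biostrings::reverseComplement(s)
            contigSeqs <- c(contigSeqs, as.character(s))
        }
        contigNames <- c(contigNames, nms)
        orient <- ifelse(rev, "-", "+")
        blockRows[[ch]] <- data.frame(
            ref_name = ch, ref_start = segStart, ref_end = segEnd,
            query_name = nms, query_start = 0,
            query_end = segEnd - segStart, orientation = orient,
            identity = 100, stringsAsFactors = FALSE)
        orderRows[[ch]] <- data.frame(
            chrom = ch, query_name = nms, orientation = orient,
            order_index = seq_len(n) - 1L, stringsAsFactors = FALSE)
        if (n > 1L)
            gapRows[[ch]] <- data.frame(
                chrom = ch, query_name = nms[-n],
                gap = segStart[-1L] - segEnd[-n],
                stringsAsFactors = FALSE)
        if (any(rev))
            invRows[[ch]] <- data.frame(
                chrom = ch, start = segStart[rev], end = segEnd[rev],
                query_name = nms[rev], stringsAsFactors = FALSE)
        if (nrow(d))
            dropRows[[ch]] <- data.frame(
                chrom = ch, start = dropStart, end = dropEnd,
                length = dropEnd - dropStart, stringsAsFactors = FALSE)
    }
    bind <- function(rows, proto) {
        if (length(rows))
            do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else proto
    }
    contigs <- Biostrings::DNAStringSet(contigSeqs)
    names(contigs) <- contigNames
    cenInterval <- if (is.null(cen))
        data.frame(chrom = character(), start = numeric(),
                   end = numeric(), stringsAsFactors = FALSE)
    else
        data.frame(chrom = cen$chrom, start = cen$position,
                   end = cen$position + cen$arrayLength,
                   stringsAsFactors = FALSE)
    truth <- new("SimTruth",
        trueBlocks = BlockSet(bind(blockRows, NULL)),
        trueOrder = bind(orderRows,
            data.frame(chrom = character(), query_name = character(),
                       orientation = character(), order_index = integer())),
        trueGaps = bind(gapRows,
            data.frame(chrom = character(), query_name = character(),
                       gap = numeric())),
        trueInversions = bind(invRows,
            data.frame(chrom = character(), start = numeric(),
                       end = numeric(), query_name = character())),
        trueDropped = bind(dropRows,
            data.frame(chrom = character(), start = numeric(),
                       end = numeric(), length = numeric())),
        centromereInterval = cenInterval)
    list(contigs = contigs, truth = truth)
}

#' Perturb truth-block identities with substitution noise
#'
#' Draws, for each truth block, a binomial number of substituted bases
#' at the given per-base rate and sets the block identity to
#' `100 * (1 - substituted / length)`.  The expected identity is
#' `100 * (1 - rate)`.  Deterministic given the seed.
#'
#' @param truth A [SimTruth-class].
#' @param rate Per-base substitution probability in [0, 1).
#' @param seed Integer seed for the draw.
#' @return The [SimTruth-class] with perturbed block identities.
#' @export
addIdentityNoise <- function(truth, rate, seed) {
    stopifnot(rate >= 0, rate < 1)
    set.seed(as.integer(seed))
    b <- blocks(truth)
    qlen <- b$query_end - b$query_start
    nsub <- rbinom(nrow(b), size = qlen, prob = rate)
    b$identity <- 100 * (1 - nsub / qlen)
    methods::initialize(truth, trueBlocks = BlockSet(b))
}

#' Simulate a fragmented assembly end-to-end
#'
#' Convenience wrapper: builds the reference, fragments it, and (when
#' `identityNoise > 0`) perturbs the truth-block identities.
#'
#' @param config A [SimConfig-class].
#' @return A list with `reference`, `contigs`, `truth` and `config`.
#' @export
#' @examples
#' sim <- simulateAssembly(simConfig(chromLengths = c(chr1 = 50000),
#'                                   nFragments = 5, seed = 7))
#' nBlocks(trueBlocks(sim$truth))
simulateAssembly <- function(config = simConfig()) {
    reference <- simulateReference(config)
    frag <- fragmentGenome(reference, config)
    if (config@identityNoise > 0)
        frag$truth <- addIdentityNoise(frag$truth, config@identityNoise,
                                       config@seed + 2L)
    list(reference = reference, contigs = frag$contigs,
         truth = frag$truth, config = config)
}
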