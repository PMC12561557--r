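## Independent brute-force oracles and random-instance generators used
## across the suite.  These deliberately use different algorithms and
## data paths than the package implementation.

## Nx/Lx by explicit accumulation loop.
bruteNxLx <- function(lengths, x) {
    sorted <- sort(as.numeric(lengths), decreasing = TRUE)
    target <- x / 100 * sum(sorted)
    acc <- 0
    for (i in seq_along(sorted)) {
        acc <- acc + sorted[i]
        if (acc >= target)
            return(list(nx = sorted[i], lx = i))
    }
    stop("unreachable")
}

## Coverage of [0, chromLen) by marking a logical base vector.
bruteCoverage <- function(df, chromLen) {
    covered <- logical(chromLen)
    for (i in seq_len(nrow(df)))
        covered[(df$ref_start[i] + 1):df$ref_end[i]] <- TRUE
    100 * sum(covered) / chromLen
}

## Reference-length-weighted identity by explicit summation.
bruteIdentity <- function(df) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(df))) {
        w <- df$ref_end[i] - df$ref_start[i]
        num <- num + df$identity[i] * w
        den <- den + w
    }
    num / den
}

## Per-chromosome Lx by explicit per-contig accumulation.
bruteChromLx <- function(df, chromLen, x) {
    sums <- c()
    for (q in unique(df$query_name))
        sums[q] <- sum(df$ref_end[df$query_name == q] -
                       df$ref_start[df$query_name == q])
    sums <- sort(sums, decreasing = TRUE)
    acc <- 0
    for (i in seq_along(sums)) {
        acc <- acc + sums[i]
        if (acc >= x / 100 * chromLen)
            return(i)
    }
    length(sums)   # shortfall convention
}

## Random block table on `nChrom` chromosomes of length `chromLen`.
randomBlockTable <- function(n, nChrom = 2, chromLen = 2e4,
                             nContigs = 5) {
    start <- sample(chromLen - 10, n, replace = TRUE)
    width <- sample(10, n, replace = TRUE)
    qstart <- sample(1000, n, replace = TRUE)
    qwidth <- sample(500, n, replace = TRUE)
    data.frame(
        ref_name = paste0("chr", sample(nChrom, n, replace = TRUE)),
        ref_start = start, ref_end = pmin(start + width, chromLen),
        query_name = paste0("ctg", sample(nContigs, n, replace = TRUE)),
        query_start = qstart, query_end = qstart + qwidth,
        orientation = sample(c("+", "-"), n, replace = TRUE),
        identity = round(runif(n, 80, 100), 3),
        stringsAsFactors = FALSE)
}

## Random DNA sequences as a named character vector.
randomSeqChars <- function(n, minLen = 5, maxLen = 200) {
    lens <- sample(minLen:maxLen, n, replace = TRUE)
    out <- vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), "")
    names(out) <- sprintf("seq%04d", seq_len(n))
    out
}

## Field-by-field PAF parser independent of readPaf (read.table based).
oraclePafParse <- function(path) {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(ref_name = tab$V6, ref_start = as.numeric(tab$V8),
               ref_end = as.numeric(tab$V9), query_name = tab$V1,
               query_start = as.numeric(tab$V3),
               query_end = as.numeric(tab$V4), orientation = tab$V5,
               identity = 100 * tab$V10 / tab$V11,
               stringsAsFactors = FALSE)
}

## A hand-assembled ScaffoldSet for writer tests.
makeScaffoldSet <- function(placements, unplaced = character()) {
    new("ScaffoldSet", placements = placements, unplaced = unplaced,
        config = evalConfig())
}
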