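mkBlocks <- function(...) BlockSet(data.frame(...))

test_that("grouping partitions and sorts blocks per chromosome", {
    bs <- mkBlocks(ref_name = c("chr2", "chr1", "chr1", "chr1"),
                   ref_start = c(10, 500, 100, 300),
                   ref_end = c(20, 600, 200, 400),
                   query_name = c("a", "b", "c", "d"),
                   query_start = 0, query_end = 10, orientation = "+")
    g <- groupBlocks(bs)
    expect_named(g, c("chr1", "chr2"))
    expect_equal(g$chr1$ref_start, c(100, 300, 500))
    expect_equal(sum(vapply(g, nrow, 0L)), nBlocks(bs))

    set.seed(201)
    big <- BlockSet(randomBlockTable(2000, nChrom = 5))
    g <- groupBlocks(big)
    expect_equal(sum(vapply(g, nrow, 0L)), 2000L)
    for (df in g) {
        expect_true(all(diff(df$ref_start) >= 0))
        ties <- which(diff(df$ref_start) == 0)
        expect_true(all(df$ref_end[ties + 1] >= df$ref_end[ties]))
    }
    expect_setequal(unlist(lapply(g, `[[`, "block_id")),
                    blocks(big)$block_id)
})

test_that("block end annotation follows the precedence rules", {
    ## degenerate full cover: both ends at the chromosome termini
    bs <- mkBlocks(ref_name = "chr1", ref_start = 0, ref_end = 1000,
                   query_name = "q1", query_start = 0, query_end = 1000,
                   orientation = "+")
    ann <- annotateBlocks(bs, c(q1 = 1000), c(chr1 = 1000))
    expect_equal(ann$left_end, "chromosome_terminus")
    expect_equal(ann$right_end, "chromosome_terminus")
    expect_true(is.na(ann$gap_to_next))

    ## a reference gap of 6000 >= the 5000 threshold marks abuts_gap
    bs <- mkBlocks(ref_name = "chr1",
                   ref_start = c(1000, 16000), ref_end = c(10000, 30000),
                   query_name = c("q1", "q2"),
                   query_start = c(100, 100), query_end = c(9100, 14100),
                   orientation = "+")
    ann <- annotateBlocks(bs, c(q1 = 20000, q2 = 20000),
                          c(chr1 = 40000))
    expect_equal(ann$gap_to_next, c(6000, NA))
    expect_equal(ann$right_end[1], "abuts_gap")
    expect_equal(ann$left_end[2], "abuts_gap")
    expect_equal(ann$right_end[2], "abuts_gap")  # 10 kb to the terminus
    expect_false(any(ann$repeat_flag))

    ## overlapping neighbours from different contigs: overlap + repeat
    bs <- mkBlocks(ref_name = "chr1",
                   ref_start = c(1000, 4000), ref_end = c(5000, 9000),
                   query_name = c("q1", "q2"),
                   query_start = c(10, 10), query_end = c(4010, 5010),
                   orientation = "+")
    ann <- annotateBlocks(bs, c(q1 = 20000, q2 = 20000),
                          c(chr1 = 40000))
    expect_equal(ann$gap_to_next[1], -1000)
    expect_equal(ann$right_end[1], "overlaps_neighbour")
    expect_equal(ann$left_end[2], "overlaps_neighbour")
    expect_true(all(ann$repeat_flag))

    ## contig terminus respects orientation
    bs <- mkBlocks(ref_name = "chr1", ref_start = 1000, ref_end = 2000,
                   query_name = "q1", query_start = 0, query_end = 1000,
                   orientation = "-")
    ann <- annotateBlocks(bs, c(q1 = 1000), c(chr1 = 40000))
    expect_equal(ann$left_end, "contig_terminus")   # query_end == qlen
    expect_equal(ann$right_end, "contig_terminus")  # query_start == 0

    expect_error(annotateBlocks(bs, c(other = 1), c(chr1 = 40000)),
                 "unknown contig 'q1'")
    expect_error(annotateBlocks(bs, c(q1 = 1000), c(chrX = 1)),
                 "unknown chromosome 'chr1'")
})

test_that("colinear chaining extends runs only under the chaining rules", {
    base <- data.frame(ref_name = "chr1",
                       ref_start = c(0, 1050, 2130),
                       ref_end = c(1000, 2000, 3000),
                       query_name = "q1",
                       query_start = c(0, 1100, 2200),
                       query_end = c(1000, 2100, 3100),
                       orientation = "+")
    runs <- findColinearRuns(BlockSet(base))
    expect_equal(nrow(runs), 1L)
    expect_equal(runs$n_blocks, 3L)
    expect_equal(c(runs$ref_start, runs$ref_end), c(0, 3000))

    mid <- base; mid$orientation[2] <- "-"
    expect_equal(nrow(findColinearRuns(BlockSet(mid))), 3L)

    ## a reference gap beyond the tolerance breaks the run
    far <- base; far$ref_start[3] <- 2e6; far$ref_end[3] <- 2e6 + 870
    runs <- findColinearRuns(BlockSet(far),
                             evalConfig(colinearGapTol = 1e5))
    expect_equal(nrow(runs), 2L)

    ## query regression breaks the run
    reg <- base; reg$query_start[3] <- 500; reg$query_end[3] <- 1500
    expect_equal(nrow(findColinearRuns(BlockSet(reg))), 2L)

    ## single block: one run containing it
    one <- findColinearRuns(BlockSet(base[1, ]))
    expect_equal(one$n_blocks, 1L)

    ## reverse runs need descending query coordinates
    rev <- data.frame(ref_name = "chr1",
                      ref_start = c(0, 1100), ref_end = c(1000, 2000),
                      query_name = "q1",
                      query_start = c(1200, 0), query_end = c(2100, 1100),
                      orientation = "-")
    expect_equal(nrow(findColinearRuns(BlockSet(rev))), 1L)

    ## every block belongs to exactly one run (conservation)
    set.seed(202)
    bs <- BlockSet(randomBlockTable(500, nChrom = 3))
    runs <- findColinearRuns(bs)
    ids <- unlist(strsplit(runs$block_ids, ",", fixed = TRUE))
    expect_setequal(ids, blocks(bs)$block_id)
    expect_equal(length(ids), nBlocks(bs))
})

test_that("inversion detection distinguishes flanked from isolated", {
    ## (+ q1), (- q1), (+ q1): the middle run is a flanked inversion
    bs <- mkBlocks(ref_name = "chr1",
                   ref_start = c(0, 2000, 4000),
                   ref_end = c(1000, 3000, 5000),
                   query_name = "q1",
                   query_start = c(0, 1500, 3000),
                   query_end = c(1000, 2500, 4000),
                   orientation = c("+", "-", "+"))
    inv <- detectInversions(findColinearRuns(bs))
    expect_equal(nrow(inv), 1L)
    expect_equal(c(inv$start, inv$end), c(2000, 3000))
    expect_equal(inv$confidence, "flanked")

    allFwd <- mkBlocks(ref_name = "chr1", ref_start = c(0, 2000),
                       ref_end = c(1000, 3000), query_name = c("a", "b"),
                       query_start = 0, query_end = 1000,
                       orientation = "+")
    expect_equal(nrow(detectInversions(findColinearRuns(allFwd))), 0L)

    ## a lone reverse contig has no same-query forward context
    lone <- mkBlocks(ref_name = "chr1", ref_start = 2000, ref_end = 3000,
                     query_name = "q9", query_start = 0, query_end = 1000,
                     orientation = "-")
    inv <- detectInversions(findColinearRuns(lone))
    expect_equal(inv$confidence, "isolated")
})

test_that("uncovered stretches are the filtered complement of the blocks", {
    bs <- mkBlocks(ref_name = "chr1", ref_start = c(0, 46000),
                   ref_end = c(40000, 100000), query_name = c("a", "b"),
                   query_start = 0, query_end = 100, orientation = "+")
    g <- uncoveredStretches(bs, c(chr1 = 100000), minLen = 5000)
    expect_equal(nrow(g), 1L)
    expect_equal(c(g$start, g$end, g$length), c(40000, 46000, 6000))

    full <- mkBlocks(ref_name = "chr1", ref_start = 0, ref_end = 1000,
                     query_name = "a", query_start = 0, query_end = 1000,
                     orientation = "+")
    expect_equal(nrow(uncoveredStretches(full, c(chr1 = 1000), 1)), 0L)

    ## a block-less chromosome is wholly uncovered
    g <- uncoveredStretches(full, c(chr1 = 1000, chr2 = 8000), 5000)
    expect_equal(g$chrom, "chr2")
    expect_equal(g$length, 8000)

    expect_error(uncoveredStretches(full, c(chr9 = 10), 1), "chr1")

    ## complement property: at minLen 1 the stretches tile the
    ## uncovered bases exactly (logical-vector oracle)
    set.seed(203)
    for (trial in 1:20) {
        df <- randomBlockTable(50, nChrom = 1, chromLen = 5000)
        df$ref_name <- "chr1"
        g <- uncoveredStretches(BlockSet(df), c(chr1 = 5000), 1)
        covered <- logical(5000)
        for (i in seq_len(nrow(df)))
            covered[(df$ref_start[i] + 1):df$ref_end[i]] <- TRUE
        inGap <- logical(5000)
        for (i in seq_len(nrow(g)))
            inGap[(g$start[i] + 1):g$end[i]] <- TRUE
        expect_identical(inGap, !covered)
    }
})

test_that("fragmentation hotspots flag dense block-boundary windows", {
    ## 30 tiny blocks inside one 1 Mb window
    set.seed(204)
    start <- sort(sample(3e5:4e5, 30))
    bs <- mkBlocks(ref_name = "chr1", ref_start = start,
                   ref_end = start + 500,
                   query_name = sprintf("t%02d", 1:30),
                   query_start = 0, query_end = 500, orientation = "+")
    hs <- fragmentationHotspots(bs, c(chr1 = 3e6))
    expect_equal(nrow(hs), 1L)
    expect_equal(c(hs$start, hs$end), c(0, 1e6))
    expect_equal(hs$n_boundaries, 60L)

    one <- mkBlocks(ref_name = "chr1", ref_start = 0, ref_end = 3e6,
                    query_name = "a", query_start = 0, query_end = 3e6,
                    orientation = "+")
    expect_equal(nrow(fragmentationHotspots(one, c(chr1 = 3e6))), 0L)

    ## adjacent hotspot windows merge
    start2 <- c(start, start + 1e6)
    bs2 <- mkBlocks(ref_name = "chr1", ref_start = start2,
                    ref_end = start2 + 500,
                    query_name = sprintf("t%02d", 1:60),
                    query_start = 0, query_end = 500, orientation = "+")
    hs2 <- fragmentationHotspots(bs2, c(chr1 = 3e6))
    expect_equal(nrow(hs2), 1L)
    expect_equal(c(hs2$start, hs2$end), c(0, 2e6))
})

test_that("per-chromosome report values follow their definitions", {
    ## coverage of a partially overlapping pair
    bs <- mkBlocks(ref_name = "chr1", ref_start = c(0, 40),
                   ref_end = c(50, 80), query_name = c("a", "b"),
                   query_start = 0, query_end = 50, orientation = "+")
    rep <- chromosomeReport(bs, c(chr1 = 100))
    expect_equal(rep$coverage_pct, 80)
    expect_equal(rep$align_start, 1)
    expect_equal(rep$align_end, 80)
    expect_equal(rep$n_blocks, 2L)

    ## weighted identity: 100 over 100 bases, 98 over 300 bases
    bs <- mkBlocks(ref_name = "chr1", ref_start = c(0, 200),
                   ref_end = c(100, 500), query_name = c("a", "b"),
                   query_start = 0, query_end = c(100, 300),
                   orientation = "+", identity = c(100, 98))
    rep <- chromosomeReport(bs, c(chr1 = 1000))
    expect_equal(rep$identity_pct, 98.5)

    ## per-chromosome L50/L90 against chromosome length
    bs <- mkBlocks(ref_name = "chr1", ref_start = c(0, 60, 92),
                   ref_end = c(60, 90, 97),
                   query_name = c("A", "B", "C"),
                   query_start = 0, query_end = c(60, 30, 5),
                   orientation = "+")
    rep <- chromosomeReport(bs, c(chr1 = 100))
    expect_equal(rep$l50, 1L)
    expect_equal(rep$l90, 2L)
    expect_false(rep$l50_shortfall || rep$l90_shortfall)

    ## unreachable 90%: Lx = n contigs and the shortfall flag is set
    rep <- chromosomeReport(mkBlocks(ref_name = "chrX", ref_start = 0,
                                     ref_end = 50, query_name = "A",
                                     query_start = 0, query_end = 50,
                                     orientation = "+"),
                            c(chrX = 100))
    expect_equal(rep$l90, 1L)
    expect_true(rep$l90_shortfall)

    ## a chromosome without blocks reports zero coverage
    rep <- chromosomeReport(bs, c(chr1 = 100, chrEmpty = 500))
    expect_equal(rep$coverage_pct[rep$chrom == "chrEmpty"], 0)
    expect_equal(rep$n_blocks[rep$chrom == "chrEmpty"], 0L)
})

test_that("report matches brute-force recomputation on random block sets", {
    set.seed(205)
    for (trial in 1:30) {
        chromLen <- sample(5000:20000, 1)
        df <- randomBlockTable(sample(5:60, 1), nChrom = 1,
                               chromLen = chromLen)
        df$ref_name <- "chr1"
        rep <- chromosomeReport(BlockSet(df), c(chr1 = chromLen))
        expect_equal(rep$coverage_pct, bruteCoverage(df, chromLen),
                     tolerance = 1e-12)
        expect_equal(rep$identity_pct, bruteIdentity(df),
                     tolerance = 1e-12)
        expect_equal(rep$l50, bruteChromLx(df, chromLen, 50))
        expect_equal(rep$l90, bruteChromLx(df, chromLen, 90))
        expect_equal(rep$n_blocks, nrow(df))
        expect_equal(rep$n_contigs, length(unique(df$query_name)))
        expect_true(rep$coverage_pct >= 0 && rep$coverage_pct <= 100)
    }
})
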