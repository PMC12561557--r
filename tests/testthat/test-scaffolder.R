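test_that("contig assignment picks the argmax chromosome with a floor", {
    bs <- BlockSet(data.frame(
        ref_name = c("chr1", "chr2"), ref_start = 0,
        ref_end = c(80000, 20000), query_name = "ctg",
        query_start = c(0, 80000), query_end = c(80000, 100000),
        orientation = "+"))
    a <- assignContigs(bs)
    expect_equal(a$assignments$chrom, "chr1")
    expect_equal(a$assignments$assign_fraction, 0.8)
    expect_length(a$unplaced, 0)

    ## a 50/50 split falls below the 0.6 confidence threshold
    bs <- BlockSet(data.frame(
        ref_name = c("chr1", "chr2"), ref_start = 0, ref_end = 50000,
        query_name = "ctg", query_start = c(0, 50000),
        query_end = c(50000, 100000), orientation = "+"))
    a <- assignContigs(bs)
    expect_equal(nrow(a$assignments), 0L)
    expect_equal(a$unplaced, "ctg")

    ## single-chromosome contig: fraction 1
    bs <- BlockSet(data.frame(
        ref_name = "chr1", ref_start = 0, ref_end = 50000,
        query_name = "ctg", query_start = 0, query_end = 50000,
        orientation = "+"))
    expect_equal(assignContigs(bs)$assignments$assign_fraction, 1)

    ## total aligned length below minContig is unplaced
    tiny <- BlockSet(data.frame(
        ref_name = "chr1", ref_start = 0, ref_end = 2000,
        query_name = "small", query_start = 0, query_end = 2000,
        orientation = "+"))
    expect_equal(assignContigs(tiny)$unplaced, "small")

    expect_error(assignContigs(BlockSet()), "no alignment blocks")
})

test_that("ordering sorts by anchor midpoint and votes orientation", {
    bs <- BlockSet(data.frame(
        ref_name = "chr1",
        ref_start = c(45000, 0, 15000),
        ref_end = c(55000, 10000, 25000),
        query_name = c("far", "near", "mid"),
        query_start = 0, query_end = 10000, orientation = "+"))
    sc <- orderAndOrient(assignContigs(bs), bs)
    p <- placements(sc)
    expect_equal(p$query_name[order(p$order_index)],
                 c("near", "mid", "far"))

    ## 70% of aligned length reverse: majority vote says reverse, and
    ## the anchor uses only the majority-orientation blocks
    bs <- BlockSet(data.frame(
        ref_name = "chr1",
        ref_start = c(0, 8000), ref_end = c(7000, 11000),
        query_name = "ctg", query_start = c(0, 7500),
        query_end = c(7000, 10500),
        orientation = c("-", "+")))
    p <- placements(orderAndOrient(assignContigs(bs), bs))
    expect_equal(p$orientation, "-")
    expect_equal(c(p$anchor_start, p$anchor_end), c(0, 7000))
})

test_that("gap inference subtracts anchors and floors overlaps", {
    p <- data.frame(query_name = c("A", "B", "C"), chrom = "chr1",
                    order_index = 0:2, orientation = "+",
                    anchor_start = c(0, 12000, 19500),
                    anchor_end = c(10000, 20000, 30000),
                    assign_fraction = 1, gap_after = NA_real_)
    sc <- inferGaps(makeScaffoldSet(p))
    g <- placements(sc)$gap_after
    expect_equal(g[1], 2000)          # positive distance kept exactly
    expect_equal(g[2], 100)           # overlap floored to minGapSize
    expect_true(is.na(g[3]))          # last contig has no gap

    ## a positive inferred gap below minGapSize is kept as inferred
    p2 <- p[1:2, ]; p2$anchor_start[2] <- 10030
    expect_equal(placements(inferGaps(makeScaffoldSet(p2)))$gap_after[1],
                 30)

    ## single placement emits no gap
    expect_true(is.na(placements(inferGaps(
        makeScaffoldSet(p[1, , drop = FALSE])))$gap_after))
})

test_that("scaffold sequences concatenate oriented contigs and N gaps", {
    p <- data.frame(query_name = c("A", "B"), chrom = "chr1",
                    order_index = 0:1, orientation = c("+", "-"),
                    anchor_start = c(0, 6), anchor_end = c(4, 8),
                    assign_fraction = 1, gap_after = c(2, NA))
    contigs <- Biostrings::DNAStringSet(c(A = "ACGT", B = "GG"))
    built <- buildScaffolds(makeScaffoldSet(p), contigs)
    expect_equal(as.character(built$sequences[["chr1_scaffold"]]),
                 "ACGTNNCC")

    ## one placed contig: scaffold equals the (revcomp'ed) contig
    p1 <- p[2, , drop = FALSE]; p1$order_index <- 0L
    p1$gap_after <- NA_real_
    built <- buildScaffolds(makeScaffoldSet(p1), contigs)
    expect_equal(as.character(built$sequences[["chr1_scaffold"]]), "CC")

    ## unplaced contigs pass through under their own names
    built <- buildScaffolds(makeScaffoldSet(p1, unplaced = "A"), contigs)
    expect_equal(as.character(built$sequences[["A"]]), "ACGT")

    expect_error(buildScaffolds(makeScaffoldSet(p), contigs["A"]),
                 "no sequence.*B")
})

test_that("scaffold length and base content are conserved", {
    set.seed(301)
    for (trial in 1:10) {
        cfg <- simConfig(chromLengths = c(c1 = 1e5, c2 = 6e4),
                         nFragments = c(8, 5),
                         minFragmentLength = 3000,
                         seed = 300 + trial)
        sim <- simulateAssembly(cfg)
        built <- scaffoldAssembly(trueBlocks(sim$truth), sim$contigs)
        p <- placements(built$scaffolds)
        for (chrom in unique(p$chrom)) {
            pc <- p[p$chrom == chrom, ]
            s <- built$sequences[[paste0(chrom, "_scaffold")]]
            gapTotal <- sum(pc$gap_after, na.rm = TRUE)
            ctgTotal <- sum(Biostrings::width(sim$contigs[pc$query_name]))
            expect_equal(length(s), ctgTotal + gapTotal)
            ## non-N base multiset equals the placed contig multiset
            ## (orientation-insensitive counts: A<->T, C<->G pairs)
            f <- Biostrings::alphabetFrequency(s)
            cf <- colSums(Biostrings::alphabetFrequency(
                sim$contigs[pc$query_name]))
            expect_equal(f[["A"]] + f[["T"]], cf[["A"]] + cf[["T"]])
            expect_equal(f[["C"]] + f[["G"]], cf[["C"]] + cf[["G"]])
            expect_equal(f[["N"]], gapTotal)
        }
    }
})

test_that("scaffolding is deterministic for fixed inputs", {
    cfg <- simConfig(chromLengths = c(c1 = 8e4), nFragments = 6,
                     seed = 9L)
    sim <- simulateAssembly(cfg)
    a <- scaffoldAssembly(trueBlocks(sim$truth), sim$contigs)
    b <- scaffoldAssembly(trueBlocks(sim$truth), sim$contigs)
    expect_identical(placements(a$scaffolds), placements(b$scaffolds))
    expect_identical(as.character(a$sequences), as.character(b$sequences))
})
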