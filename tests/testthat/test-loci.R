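test_that("coverage matches the per-position definition", {
    ## no reads: all-zero depth
    empty <- readsGRanges(data.frame(chrom = character(0),
                                     start = integer(0), end = integer(0)))
    cov0 <- computeCoverage(empty, seqlengths = c(chr1 = 100L))
    expect_identical(sum(as.integer(cov0$chr1)), 0L)

    ## a single read [10, 30)
    one <- readsGRanges(data.frame(chrom = "chr1", start = 10, end = 30),
                        seqlen = c(chr1 = 100L))
    d <- as.integer(computeCoverage(one)$chr1)
    expect_identical(d, c(rep(0L, 10), rep(1L, 20), rep(0L, 70)))

    ## 50 random reads vs brute force
    set.seed(31)
    df <- data.frame(chrom = "chr1", start = sample(0:960, 50, TRUE))
    df$end <- df$start + sample(18:24, 50, TRUE)
    reads <- readsGRanges(df)
    d <- as.integer(computeCoverage(reads)$chr1)
    expect_identical(d, oracleCoverage(df$start, df$end, 1000L))
})

test_that("reads beyond the chromosome end are an error", {
    bad <- suppressWarnings(
        readsGRanges(data.frame(chrom = "chr1", start = 990, end = 1011)))
    expect_error(suppressWarnings(computeCoverage(bad)), "beyond")
})

test_that("island detection keeps maximal runs with peak depth >= 3", {
    depth <- c(0, 1, 3, 3, 0, 2, 2, 0)
    cov <- IRanges::RleList(chr1 = S4Vectors::Rle(depth))
    isl <- detectIslands(cov)
    expect_length(isl, 1)
    expect_identical(GenomicRanges::start(isl), 2L)  # run [2,4] holds the 3s
    expect_identical(GenomicRanges::end(isl), 4L)
    expect_identical(isl$peak_coverage, 3L)
    ## peak exactly 2 is discarded; all-zero yields nothing
    expect_length(detectIslands(IRanges::RleList(chr1 = S4Vectors::Rle(
        c(0, 2, 2, 0)))), 0)
    expect_length(detectIslands(IRanges::RleList(chr1 = S4Vectors::Rle(
        rep(0, 10)))), 0)
})

test_that("island detection agrees with a run-scan oracle", {
    set.seed(41)
    for (rep in 1:10) {
        depth <- sample(0:5, 200, TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.05,
                                                 0.05))
        isl <- detectIslands(IRanges::RleList(chr1 = S4Vectors::Rle(depth)))
        ref <- oracleIslands(depth)
        expect_identical(length(isl), nrow(ref))
        if (nrow(ref)) {
            expect_identical(GenomicRanges::start(isl), unname(ref[, "start"]))
            expect_identical(GenomicRanges::end(isl), unname(ref[, "end"]))
            expect_identical(isl$peak_coverage, as.integer(ref[, "peak"]))
        }
    }
})

.design2 <- S4Vectors::DataFrame(library_id = c("L1", "L2"),
                                 tissue = "cartilage",
                                 condition = c("H", "OC"))

test_that("read counting enforces the 50% overlap rule", {
    islands <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = c(101, 301), end = c(140, 340)),
        seqlengths = c(chr1 = 1000L))
    names(islands) <- c("i1", "i2")
    islands$peak_coverage <- 5L
    ## read 40% inside i1: 8 of 20 bases in [100,140)
    reads <- readsGRanges(data.frame(
        chrom = "chr1", start = c(132, 110, 305), end = c(152, 130, 325),
        read_id = c("border", "inside", "inside2"),
        library_id = c("L1", "L1", "L2")))
    se <- countReads(islands, reads, .design2)
    m <- SummarizedExperiment::assay(se, "counts")
    expect_identical(m["i1", "L1"], 1L)   # only the fully-inside read
    expect_identical(m["i2", "L2"], 1L)
    expect_identical(sum(m), 2L)

    ## no reads: zero matrix of the right shape
    se0 <- countReads(islands, reads[0], .design2)
    expect_identical(dim(SummarizedExperiment::assay(se0)), c(2L, 2L))
    expect_identical(sum(SummarizedExperiment::assay(se0)), 0L)

    ## unknown library errors
    bad <- readsGRanges(data.frame(chrom = "chr1", start = 110, end = 130,
                                   read_id = "x", library_id = "L9"))
    expect_error(countReads(islands, bad, .design2), "L9")
})

test_that("a hand-enumerated fixture of 12 reads over 3 islands counts exactly", {
    islands <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = c(101, 201, 301),
                                 end = c(130, 230, 330)),
        seqlengths = c(chr1 = 1000L))
    names(islands) <- c("a", "b", "c")
    islands$peak_coverage <- 3L
    df <- data.frame(
        chrom = "chr1",
        start = c(100, 105, 110, 95, 200, 205, 210, 215, 220, 300, 305, 390),
        end = c(120, 125, 130, 115, 220, 225, 230, 235, 240, 320, 325, 410),
        read_id = sprintf("r%02d", 1:12),
        library_id = rep(c("L1", "L2"), 6))
    ## by hand: island a gets r01,r02,r03 and r04 (15/20 bases inside);
    ## island b gets r05..r09 (r09: 10/20 = 50%, counted);
    ## island c gets r10 and r11; r12 misses everything.
    se <- countReads(islands, readsGRanges(df), .design2)
    m <- SummarizedExperiment::assay(se, "counts")
    expect_identical(unname(m["a", ]), c(2L, 2L))
    expect_identical(unname(m["b", ]), c(3L, 2L))
    expect_identical(unname(m["c", ]), c(1L, 1L))
})

test_that("island detection is invariant under read order permutation", {
    set.seed(53)
    df <- data.frame(chrom = "chr1", start = sample(0:960, 60, TRUE))
    df$end <- df$start + 21
    reads <- readsGRanges(df)
    i1 <- detectIslands(computeCoverage(reads))
    i2 <- detectIslands(computeCoverage(reads[sample(60)]))
    expect_identical(GenomicRanges::start(i1), GenomicRanges::start(i2))
    expect_identical(GenomicRanges::end(i1), GenomicRanges::end(i2))
})

test_that("assigned counts never exceed retained read placements", {
    set.seed(61)
    df <- data.frame(chrom = "chr1", start = sample(0:960, 80, TRUE),
                     library_id = sample(c("L1", "L2"), 80, TRUE))
    df$end <- df$start + sample(18:24, 80, TRUE)
    df$read_id <- sprintf("r%03d", 1:80)
    reads <- readsGRanges(df)
    isl <- detectIslands(computeCoverage(reads))
    se <- countReads(isl, reads, .design2)
    expect_lte(sum(SummarizedExperiment::assay(se)), length(reads))
})
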