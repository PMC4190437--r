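toyGenome <- function(seed = 101, len = 500L) {
    set.seed(seed)
    Biostrings::DNAStringSet(c(chr1 = paste(
        sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")))
}

test_that("window excision anchors on island boundaries", {
    genome <- toyGenome()
    isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 120),
                                  strand = "+",
                                  seqlengths = c(chr1 = 500L))
    names(isl) <- "i1"
    w <- exciseWindows(isl, genome)
    expect_length(w, 2)
    ## island [100,120) 0-based: windows [90,170) and [50,130)
    expect_identical(GenomicRanges::start(w), c(91L, 51L))
    expect_identical(GenomicRanges::end(w), c(170L, 130L))
    expect_identical(w$window_kind, c("5p-sim", "3p-sim"))
    chr <- as.character(genome)[["chr1"]]
    expect_identical(w$sequence, c(substring(chr, 91, 170),
                                   substring(chr, 51, 130)))
})

test_that("window excision clamps at chromosome bounds", {
    genome <- toyGenome()
    isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 25),
                                  seqlengths = c(chr1 = 500L))
    names(isl) <- "edge"
    w <- exciseWindows(isl, genome)
    expect_identical(GenomicRanges::start(w), c(1L, 1L))  # clamped at 0
    expect_identical(GenomicRanges::end(w), c(75L, 35L))
})

test_that("minus-strand islands give reverse-complemented swapped windows", {
    genome <- toyGenome()
    isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 220),
                                  strand = "-",
                                  seqlengths = c(chr1 = 500L))
    names(isl) <- "m"
    w <- exciseWindows(isl, genome)
    chr <- as.character(genome)[["chr1"]]
    ## plus-strand slice of [190,270) reverse-complemented, roles swapped
    expect_identical(w$window_kind, c("3p-sim", "5p-sim"))
    expect_identical(w$sequence[1], revcomp(substring(chr, 191, 270)))
    expect_identical(w$sequence[2], revcomp(substring(chr, 151, 230)))
    expect_error(exciseWindows(
        GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10)), genome),
        "absent")
})

test_that("known-miRNA annotation picks the nearest-midpoint overlap", {
    isl <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = c(101, 501, 901),
                                 width = 20),
        seqlengths = c(chr1 = 2000L))
    names(isl) <- c("i1", "i2", "i3")
    ann <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = c(95, 111, 700), width = 22))
    ann$feature_class <- c("miRNA", "miRNA", "miRNA")
    ann$name <- c("mir-a", "mir-b", "mir-c")
    got <- annotateKnown(isl, ann)
    ## i1 overlaps both; mir-a midpoint 105.5 vs mir-b 121.5, island mid 110.5
    expect_identical(got, c("mir-a", NA, NA))
    ## ncRNA-class annotations never label islands
    ann$feature_class <- "ncRNA"
    expect_identical(annotateKnown(isl, ann), rep(NA_character_, 3))
})

test_that("annotation agrees with an all-pairs overlap scan", {
    set.seed(71)
    for (rep in 1:5) {
        isl <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(start = sample(1:900, 15), width = 21),
            seqlengths = c(chr1 = 1000L))
        names(isl) <- sprintf("i%02d", 1:15)
        ann <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(start = sample(1:900, 10),
                                     width = sample(18:40, 10, TRUE)))
        ann$feature_class <- "miRNA"
        ann$name <- sprintf("mir-%02d", 1:10)
        got <- annotateKnown(isl, ann)
        for (k in 1:15) {
            s <- GenomicRanges::start(isl)[k]; e <- GenomicRanges::end(isl)[k]
            ov <- which(GenomicRanges::start(ann) <= e &
                            GenomicRanges::end(ann) >= s)
            if (!length(ov)) {
                expect_true(is.na(got[k]))
            } else {
                mid <- (s + e) / 2
                amid <- (GenomicRanges::start(ann)[ov] +
                             GenomicRanges::end(ann)[ov]) / 2
                expect_identical(got[k], ann$name[ov[which.min(abs(amid -
                                                                       mid))]])
            }
        }
    }
})

test_that("local alignment scores match an independent affine-gap DP", {
    set.seed(83)
    ## identical sequences: every match contributes +1
    s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    expect_identical(alignPrecursor(s, s)$score, 100)
    for (k in 1:20) {
        a <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
        b <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
        expect_equal(alignPrecursor(a, b)$score, oracleLocalAlign(a, b),
                     label = paste(a, "vs", b))
    }
    expect_error(alignPrecursor("", "ACGT"), "non-empty")
})

test_that("the bit-score conservation cutoff is exclusive at 90", {
    lambda <- 1.28; K <- 0.46
    sAt <- (90 * log(2) + log(K)) / lambda   # raw score giving bits = 90
    expect_equal(bitScore(sAt), 90)
    ## raw scores are integers in practice; check both sides of the cutoff
    below <- floor(sAt); above <- ceiling(sAt)
    expect_false(bitScore(below) > 90)
    expect_true(bitScore(above) > 90)
})

test_that("novel classification applies all four filters", {
    base <- list(mfe = -25, hairpin = TRUE, matureLen = 22L,
                 libCounts = c(L1 = 1500, L2 = 10))
    call1 <- classifyNovel(base$mfe, base$hairpin, base$matureLen,
                           base$libCounts)
    expect_identical(call1$status, "novel")
    ## count 999 in the best library fails the abundance filter
    c2 <- classifyNovel(-25, TRUE, 22L, c(999, 10))
    expect_identical(c2$status, "rejected")
    expect_false(c2$count_ok)
    ## mature length 30 fails the size filter
    c3 <- classifyNovel(-25, TRUE, 30L, c(2000, 10))
    expect_false(c3$size_ok)
    ## -19.5 fails the energy filter, -20 exactly also fails (strict)
    expect_false(classifyNovel(-19.5, TRUE, 22L, 2000)$energy_ok)
    expect_false(classifyNovel(-20, TRUE, 22L, 2000)$energy_ok)
    ## boundary: count exactly 1000 passes
    expect_true(classifyNovel(-25, TRUE, 22L, 1000)$count_ok)
})

test_that("discovery folds both windows and keeps the lower-energy one", {
    cfg <- simulationConfig(seed = 29, nPrecursors = 3L,
                            conditions = c(H = 2L, OC = 2L),
                            chromLengths = c(chr1 = 8000L),
                            meanRange = c(1500, 3000),
                            nDecoyNcrna = 0L, nDecoyExpressed = 1L,
                            backgroundPerKb = 0)
    sim <- simulateMirnaExperiment(cfg)
    reads <- filterMultimappers(simReads(sim))
    se <- countReads(detectIslands(computeCoverage(reads)), reads,
                     simDesign(sim))
    islands <- SummarizedExperiment::rowRanges(se)
    w <- exciseWindows(islands, simGenome(sim))
    expect_identical(length(w), 2L * length(islands))
    disc <- discoverMirnas(se, simGenome(sim))
    for (k in seq_along(islands)) {
        wk <- w[w$island == names(islands)[k]]
        mfes <- vapply(wk$sequence,
                       function(s) foldMfe(s)$mfe, numeric(1))
        expect_equal(disc$mfe[k], min(mfes))
    }
    ## known annotation overrides novel status
    ann <- GenomicRanges::granges(simPrecursors(sim))
    ann$feature_class <- "miRNA"
    ann$name <- paste0("eca-", names(simPrecursors(sim)))
    disc2 <- discoverMirnas(se, simGenome(sim), annotations = ann)
    hit <- !is.na(disc2$known_name)
    expect_true(any(hit))
    expect_true(all(disc2$status[hit] == "known"))
})
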