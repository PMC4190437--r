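smallConfig <- function(seed, ...) {
    simulationConfig(seed = seed, nPrecursors = 4L,
                     conditions = c(H = 2L, OC = 2L),
                     chromLengths = c(chr1 = 8000L),
                     meanRange = c(20, 60), nDecoyNcrna = 2L,
                     nDecoyExpressed = 2L, backgroundPerKb = 0.5, ...)
}

test_that("the generator is deterministic for a fixed seed", {
    g1 <- generateGenome(smallConfig(1))
    g2 <- generateGenome(smallConfig(1))
    expect_identical(as.character(g1), as.character(g2))
    expect_false(identical(as.character(generateGenome(smallConfig(2))),
                           as.character(g1)))

    sim1 <- simulateMirnaExperiment(smallConfig(5))
    sim2 <- simulateMirnaExperiment(smallConfig(5))
    expect_identical(S4Vectors::mcols(simReads(sim1)),
                     S4Vectors::mcols(simReads(sim2)))
    expect_identical(simTrueCounts(sim1), simTrueCounts(sim2))

    ## byte-identical SAM output
    d1 <- tempfile(); d2 <- tempfile()
    writeSimulation(sim1, d1); writeSimulation(sim2, d2)
    expect_identical(readLines(file.path(d1, "H_1.sam")),
                     readLines(file.path(d2, "H_1.sam")))
})

test_that("degenerate genome requests are rejected", {
    expect_error(simulationConfig(seed = 1, chromLengths = c(chr1 = 0L)),
                 "positive")
    cfg <- simulationConfig(seed = 1)
    cfg@chromLengths <- c(chr1 = 150L)
    expect_error(generateGenome(cfg), ">= 200")
    expect_silent(generateGenome(simulationConfig(
        seed = 1, chromLengths = c(chr1 = 250L))))
})

test_that("planting zero precursors leaves the genome unchanged", {
    cfg <- smallConfig(3)
    cfg@nPrecursors <- 0L
    cfg@nDecoyNcrna <- 0L
    cfg@nDecoyExpressed <- 0L
    g <- generateGenome(cfg)
    out <- plantPrecursors(g, cfg)
    expect_identical(as.character(out$genome), as.character(g))
    expect_length(out$precursors, 0)
    expect_length(out$decoys, 0)
})

test_that("an overcrowded genome raises a placement error", {
    cfg <- simulationConfig(seed = 2, nPrecursors = 60L,
                            chromLengths = c(chr1 = 2000L),
                            nDecoyNcrna = 0L, nDecoyExpressed = 0L)
    g <- generateGenome(cfg)
    expect_error(plantPrecursors(g, cfg), "too small")
})

test_that("planted precursors are genuine low-energy hairpins", {
    cfg <- smallConfig(7)
    sim <- simulateMirnaExperiment(cfg)
    prec <- simPrecursors(sim)
    chr <- as.character(simGenome(sim))[["chr1"]]
    for (k in seq_along(prec)) {
        s <- substring(chr, GenomicRanges::start(prec)[k],
                       GenomicRanges::end(prec)[k])
        if (as.character(GenomicRanges::strand(prec))[k] == "-")
            s <- revcomp(s)
        f <- foldMfe(s)
        expect_lt(f$mfe, -20)
        expect_true(isHairpin(f$structure))
    }
    ## mature arms fall inside the precursor (validity is also checked
    ## at construction)
    expect_true(all(prec$mature5p_start >= GenomicRanges::start(prec) - 1L &
                        prec$mature5p_end <= GenomicRanges::end(prec)))
})

test_that("true counts equal emitted non-background reads per library", {
    sim <- simulateMirnaExperiment(smallConfig(9))
    reads <- simReads(sim)
    primary <- reads[reads$primary]
    tc <- simTrueCounts(sim)
    for (lib in simDesign(sim)$library_id) {
        sub <- primary[primary$library_id == lib & !is.na(primary$locus)]
        expect_identical(length(sub), sum(tc[, lib]))
        tab <- table(sub$locus)
        expect_identical(as.integer(tab[rownames(tc)[rownames(tc) %in%
                                                         names(tab)]]),
                         unname(tc[rownames(tc) %in% names(tab), lib]))
    }
})

test_that("a zero multimapper rate yields unique alignments only", {
    cfg <- smallConfig(11, multimapperRate = 0)
    cfg@backgroundPerKb <- 0
    sim <- simulateMirnaExperiment(cfg)
    expect_true(all(simReads(sim)$n_alignments == 1L))
    expect_true(all(simReads(sim)$primary))
})

test_that("a zero-mean locus emits no reads", {
    cfg <- smallConfig(13)
    sim <- simulateMirnaExperiment(cfg)
    ## force a zero-mean locus by rebuilding with capped zero counts
    cfg2 <- smallConfig(13, nLowExpressed = 2L, lowExpressedCap = 0L)
    sim2 <- simulateMirnaExperiment(cfg2)
    capped <- names(simPrecursors(sim2))[simPrecursors(sim2)$low_expressed]
    expect_true(all(simTrueCounts(sim2)[capped, ] == 0L))
    expect_false(any(simReads(sim2)$locus %in% capped))
})

test_that("simulated counts reproduce the NB moments", {
    ## one locus, NB mean 100, dispersion 0.1, 400 replicate libraries
    cfg <- simulationConfig(seed = 17, nPrecursors = 1L,
                            conditions = c(H = 400L),
                            chromLengths = c(chr1 = 2000L),
                            meanRange = c(100, 100),
                            dispersionRange = c(0.1, 0.1),
                            sizeFactorRange = c(1, 1),
                            deFraction = 0, backgroundPerKb = 0,
                            multimapperRate = 0,
                            nDecoyNcrna = 0L, nDecoyExpressed = 0L)
    sim <- simulateMirnaExperiment(cfg)
    k <- as.numeric(simTrueCounts(sim))
    n <- length(k)
    se <- sqrt((100 + 0.1 * 100^2) / n)
    expect_lt(abs(mean(k) - 100), 3 * se)
})

test_that("unknown DE condition labels are rejected", {
    cfg <- smallConfig(19)
    cfg@deConditions <- "NOPE"
    g <- generateGenome(cfg)
    tr <- plantPrecursors(g, cfg)
    expect_error(simulateLibraries(tr$genome, tr, cfg), "NOPE")
})
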