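## Synthetic small-RNA experiment generator. Plants designed stem-loop
## precursors and decoy loci in a uniform-random toy genome, then emits
## per-library aligned reads whose per-locus counts follow a negative
## binomial law with known means, dispersions, fold changes and library
## size factors. Everything downstream of the single master seed is
## deterministic; stage-level sub-seeds are derived from it by fixed
## offsets (all < 2^31).

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed %% .Machine$integer.max)
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    expr
}

.randomBases <- function(n, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    sample(names(p), n, replace = TRUE, prob = p)
}

.revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a uniform-random toy genome
#'
#' @param config a \linkS4class{SimulationConfig}; chromosome names and
#'   lengths come from \code{chromLengths} (each must be >= 200 nt).
#' @return A \code{DNAStringSet}, one entry per chromosome.
#' @examples
#' g <- generateGenome(simulationConfig(seed = 1))
#' @export
generateGenome <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    if (any(config@chromLengths < 200L))
        stop("chromosome lengths must be >= 200 nt")
    .withSeed(config@seed + 101L, {
        seqs <- vapply(config@chromLengths, function(L)
            paste(.randomBases(L), collapse = ""), character(1))
        genome <- Biostrings::DNAStringSet(seqs)
        names(genome) <- names(config@chromLengths)
        genome
    })
}

## Sample nFeatures non-overlapping start positions for features of the
## given widths, keeping >= margin nt clear of chromosome edges and
## >= minGap nt between features. Rejection sampling; errors out when the
## genome cannot host the request.
.placeFeatures <- function(chromLengths, widths, margin = 100L,
                           minGap = 120L, maxTries = 20000L) {
    n <- length(widths)
    if (n == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
                          width = integer(0)))
    placed <- data.frame(chrom = character(0), start = integer(0),
                         width = integer(0), stringsAsFactors = FALSE)
    probs <- chromLengths / sum(chromLengths)
    tries <- 0L
    while (nrow(placed) < n) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("genome too small to host ", n,
                 " features without overlap; enlarge 'chromLengths'")
        w <- widths[nrow(placed) + 1L]
        chrom <- sample(names(chromLengths), 1L, prob = probs)
        L <- chromLengths[[chrom]]
        lo <- margin
        hi <- L - margin - w
        if (hi <= lo) next
        s <- sample(lo:hi, 1L)
        same <- placed[placed$chrom == chrom, , drop = FALSE]
        if (nrow(same) &&
            any(s < same$start + same$width + minGap &
                same$start < s + w + minGap)) next
        placed <- rbind(placed,
                        data.frame(chrom = chrom, start = s, width = w,
                                   stringsAsFactors = FALSE))
    }
    placed
}

#' Plant hairpin precursors and decoy loci in a genome
#'
#' Each planted precursor is a designed stem-loop: a GC-rich 5' arm, a
#' short terminal loop, and the exact reverse complement of the arm as the
#' 3' arm, so the stem is perfectly complementary and folds far below the
#' -20 kcal/mol energy cutoff characteristic of miRNA precursors. The
#' mature 5p and 3p arms are the outer \code{matureLen} nt of each stem
#' arm. Precursors are placed on random strands, non-overlapping, clear of
#' chromosome edges. Decoy loci (annotated non-miRNA ncRNAs and
#' unannotated expressed loci) reserve intervals of untouched random
#' sequence.
#'
#' @param genome a \code{DNAStringSet} from \code{\link{generateGenome}}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{genome} (modified \code{DNAStringSet}),
#'   \code{precursors} (\code{GRanges} with geometry, mature intervals
#'   (0-based half-open in metadata columns), source arm, DE flag, fold
#'   change) and \code{decoys} (\code{GRanges} with \code{feature_class}).
#' @export
plantPrecursors <- function(genome, config) {
    stopifnot(is(genome, "DNAStringSet"), is(config, "SimulationConfig"))
    chromLengths <- setNames(Biostrings::width(genome), names(genome))
    .withSeed(config@seed + 202L, {
        np <- config@nPrecursors
        stems <- if (np) sample(config@stemRange[1]:config@stemRange[2],
                                np, replace = TRUE) else integer(0)
        loops <- if (np) sample(config@loopRange[1]:config@loopRange[2],
                                np, replace = TRUE) else integer(0)
        precWidths <- 2L * stems + loops
        decoyWidths <- c(rep(80L, config@nDecoyNcrna),
                         rep(100L, config@nDecoyExpressed))
        placed <- .placeFeatures(chromLengths, c(precWidths, decoyWidths))
        precPlaced <- placed[seq_len(np), , drop = FALSE]
        decoyPlaced <- placed[np + seq_along(decoyWidths), , drop = FALSE]

        mlen <- config@matureLen
        precList <- vector("list", np)
        for (k in seq_len(np)) {
            arm5 <- paste(.randomBases(stems[k], gc = config@armGC),
                          collapse = "")
            loop <- paste(.randomBases(loops[k], gc = 0.3), collapse = "")
            prec <- paste0(arm5, loop, .revcompChr(arm5))
            strand <- sample(c("+", "-"), 1L)
            insert <- if (strand == "+") prec else .revcompChr(prec)
            chrom <- precPlaced$chrom[k]
            s0 <- precPlaced$start[k]            # 0-based start
            w <- nchar(prec)
            genome[[chrom]] <- Biostrings::replaceAt(
                genome[[chrom]], IRanges::IRanges(s0 + 1L, s0 + w), insert)
            armLen <- stems[k]
            m <- min(mlen, armLen)
            if (strand == "+") {
                m5 <- c(s0, s0 + m)
                m3 <- c(s0 + w - m, s0 + w)
            } else {
                m5 <- c(s0 + w - m, s0 + w)
                m3 <- c(s0, s0 + m)
            }
            precList[[k]] <- data.frame(
                chrom = chrom, start = s0, end = s0 + w, strand = strand,
                stem_len = stems[k], loop_len = loops[k],
                mature5p_start = m5[1], mature5p_end = m5[2],
                mature3p_start = m3[1], mature3p_end = m3[2],
                source_arm = sample(c("5p", "3p"), 1L, prob = c(0.8, 0.2)),
                stringsAsFactors = FALSE)
        }
        precDf <- if (np) do.call(rbind, precList) else
            data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       stem_len = integer(0), loop_len = integer(0),
                       mature5p_start = integer(0), mature5p_end = integer(0),
                       mature3p_start = integer(0), mature3p_end = integer(0),
                       source_arm = character(0))
        precursors <- GenomicRanges::GRanges(
            precDf$chrom,
            IRanges::IRanges(start = precDf$start + 1L, end = precDf$end),
            strand = precDf$strand,
            seqlengths = chromLengths)
        S4Vectors::mcols(precursors) <- S4Vectors::DataFrame(
            precDf[, setdiff(colnames(precDf),
                             c("chrom", "start", "end", "strand")),
                   drop = FALSE])
        if (np) {
            names(precursors) <- sprintf("mir_%03d", seq_len(np))
            nde <- round(config@deFraction * np)
            de <- rep(FALSE, np)
            if (nde) de[sample(np, nde)] <- TRUE
            precursors$is_de <- de
            precursors$fold_change <- ifelse(de, config@foldChange, 1)
            low <- rep(FALSE, np)
            if (config@nLowExpressed)
                low[sample(np, config@nLowExpressed)] <- TRUE
            precursors$low_expressed <- low
        } else {
            precursors$is_de <- logical(0)
            precursors$fold_change <- numeric(0)
            precursors$low_expressed <- logical(0)
        }

        ## decoy loci are *non-hairpin* by construction: resample any
        ## placement whose surrounding region folds below the -20 kcal/mol
        ## precursor cutoff under default energy parameters (the MFE of a
        ## sub-window can never undercut the MFE of the enclosing region,
        ## so every excised window around such a decoy stays above -20)
        chrStr <- setNames(as.character(genome), names(genome))
        defP <- defaultEnergyParams()
        decoyOk <- function(chrom, s0, w) {
            lo <- max(0L, s0 - 25L)
            hi <- min(chromLengths[[chrom]], s0 + w + 25L)
            foldMfe(substring(chrStr[[chrom]], lo + 1L, hi), defP)$mfe >= -20
        }
        taken <- rbind(precPlaced, decoyPlaced)
        for (k in seq_len(nrow(decoyPlaced))) {
            tries <- 0L
            while (!decoyOk(decoyPlaced$chrom[k], decoyPlaced$start[k],
                            decoyPlaced$width[k])) {
                tries <- tries + 1L
                if (tries > 2000L)
                    stop("could not place a structure-free decoy locus")
                w <- decoyPlaced$width[k]
                chrom <- sample(names(chromLengths), 1L,
                                prob = chromLengths / sum(chromLengths))
                s <- sample(100L:(chromLengths[[chrom]] - 100L - w), 1L)
                other <- taken[-(nrow(precPlaced) + k), , drop = FALSE]
                same <- other[other$chrom == chrom, , drop = FALSE]
                if (nrow(same) &&
                    any(s < same$start + same$width + 120L &
                        same$start < s + w + 120L)) next
                decoyPlaced$chrom[k] <- chrom
                decoyPlaced$start[k] <- s
                taken[nrow(precPlaced) + k, c("chrom", "start")] <-
                    list(chrom, s)
            }
        }
        decoys <- GenomicRanges::GRanges(
            decoyPlaced$chrom,
            IRanges::IRanges(start = decoyPlaced$start + 1L,
                             width = decoyPlaced$width),
            strand = rep("+", nrow(decoyPlaced)),
            seqlengths = chromLengths)
        decoys$feature_class <- c(rep("ncRNA", config@nDecoyNcrna),
                                  rep("decoy_expr", config@nDecoyExpressed))
        if (length(decoys))
            names(decoys) <- sprintf("decoy_%03d", seq_along(decoys))
        list(genome = genome, precursors = precursors, decoys = decoys)
    })
}

.libraryIds <- function(conditions) {
    unlist(lapply(names(conditions), function(cond)
        if (conditions[[cond]] > 0L)
            paste(cond, seq_len(conditions[[cond]]), sep = "_")
        else character(0)), use.names = FALSE)
}

#' Simulate multi-library aligned small-RNA reads
#'
#' Draws per-locus per-library counts from negative binomial laws
#' NB(mean = base mean x true size factor x fold change for DE loci in the
#' affected conditions, dispersion as configured) and emits each counted
#' read as an aligned placement on the expressed mature arm with up to
#' \code{jitter} nt of 5'-end offset. A configured fraction of reads is
#' duplicated to 2-8 alignment positions (NH > 1, best placement first) to
#' exercise the multimapper filter; background reads are scattered
#' uniformly; annotated decoy ncRNA loci receive moderate expression so the
#' ncRNA-exclusion filter has work to do.
#'
#' @param genome \code{DNAStringSet} with planted features.
#' @param truth the list returned by \code{\link{plantPrecursors}}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MirSimulation}.
#' @export
simulateLibraries <- function(genome, truth, config) {
    stopifnot(is(genome, "DNAStringSet"), is(config, "SimulationConfig"))
    if (!all(config@deConditions %in% names(config@conditions)))
        stop("unknown condition label(s): ",
             paste(setdiff(config@deConditions, names(config@conditions)),
                   collapse = ", "))
    chromLengths <- setNames(Biostrings::width(genome), names(genome))
    precursors <- truth$precursors
    decoys <- truth$decoys
    .withSeed(config@seed + 303L, {
        libs <- .libraryIds(config@conditions)
        cond <- rep(names(config@conditions), config@conditions)
        design <- S4Vectors::DataFrame(library_id = libs,
                                       tissue = config@tissue,
                                       condition = cond)
        nlib <- length(libs)
        sf <- runif(nlib, config@sizeFactorRange[1], config@sizeFactorRange[2])
        names(sf) <- libs

        ## truth loci: precursors, then expressed decoys, then ncRNA decoys
        exprDecoys <- decoys[decoys$feature_class == "decoy_expr"]
        ncrnaDecoys <- decoys[decoys$feature_class == "ncRNA"]
        np <- length(precursors)
        ne <- length(exprDecoys)
        nn <- length(ncrnaDecoys)
        nloc <- np + ne + nn
        locusIds <- c(names(precursors), names(exprDecoys),
                      names(ncrnaDecoys))
        lu <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))
        baseMean <- c(lu(np, config@meanRange), lu(ne, config@meanRange),
                      rep(50, nn))
        dispersion <- runif(nloc, config@dispersionRange[1],
                            config@dispersionRange[2])

        trueMeans <- matrix(0, nloc, nlib,
                            dimnames = list(locusIds, libs))
        for (j in seq_len(nlib)) {
            fc <- rep(1, nloc)
            if (np && cond[j] %in% config@deConditions)
                fc[seq_len(np)] <- precursors$fold_change
            trueMeans[, j] <- baseMean * fc * sf[j]
        }

        counts <- matrix(0L, nloc, nlib, dimnames = list(locusIds, libs))
        for (j in seq_len(nlib)) {
            mu <- trueMeans[, j]
            k <- ifelse(dispersion > 0,
                        rnbinom(nloc, mu = mu, size = 1 / dispersion),
                        rpois(nloc, mu))
            counts[, j] <- as.integer(k)
        }
        counts[trueMeans == 0] <- 0L
        if (np && any(precursors$low_expressed)) {
            capIdx <- which(precursors$low_expressed)
            counts[capIdx, ] <- pmin(counts[capIdx, , drop = FALSE],
                                     config@lowExpressedCap)
        }

        ## source interval per locus (0-based half-open)
        srcChrom <- character(nloc); srcStart <- integer(nloc)
        srcEnd <- integer(nloc); srcStrand <- character(nloc)
        if (np) {
            is5p <- precursors$source_arm == "5p"
            srcChrom[seq_len(np)] <- as.character(
                GenomicRanges::seqnames(precursors))
            srcStart[seq_len(np)] <- ifelse(is5p, precursors$mature5p_start,
                                            precursors$mature3p_start)
            srcEnd[seq_len(np)] <- ifelse(is5p, precursors$mature5p_end,
                                          precursors$mature3p_end)
            srcStrand[seq_len(np)] <- as.character(
                GenomicRanges::strand(precursors))
        }
        for (k in seq_len(ne)) {
            g <- exprDecoys[k]
            s0 <- GenomicRanges::start(g) - 1L + 30L
            srcChrom[np + k] <- as.character(GenomicRanges::seqnames(g))
            srcStart[np + k] <- s0
            srcEnd[np + k] <- s0 + config@matureLen
            srcStrand[np + k] <- "+"
        }
        for (k in seq_len(nn)) {
            g <- ncrnaDecoys[k]
            s0 <- GenomicRanges::start(g) - 1L + 20L
            srcChrom[np + ne + k] <- as.character(GenomicRanges::seqnames(g))
            srcStart[np + ne + k] <- s0
            srcEnd[np + ne + k] <- s0 + config@matureLen
            srcStrand[np + ne + k] <- "+"
        }

        ## emit reads
        rows <- list()
        readCounter <- 0L
        jit <- config@jitter
        for (j in seq_len(nlib)) {
            for (i in seq_len(nloc)) {
                nread <- counts[i, j]
                if (nread == 0L) next
                shift <- if (jit > 0L)
                    sample(seq(-jit, jit), nread, replace = TRUE)
                else rep(0L, nread)
                if (srcStrand[i] == "-") {
                    rs <- rep(srcStart[i], nread)
                    re <- srcEnd[i] + shift
                } else {
                    rs <- srcStart[i] + shift
                    re <- rep(srcEnd[i], nread)
                }
                nh <- rep(1L, nread)
                nmm <- rbinom(1, nread, config@multimapperRate)
                if (nmm > 0L)
                    nh[sample(nread, nmm)] <- sample(2:8, nmm, replace = TRUE)
                ids <- sprintf("r%08d", readCounter + seq_len(nread))
                readCounter <- readCounter + nread
                rows[[length(rows) + 1L]] <- data.frame(
                    read_id = ids, library_id = libs[j],
                    chrom = srcChrom[i], start = rs, end = re,
                    strand = srcStrand[i], n_alignments = nh,
                    locus = locusIds[i], primary = TRUE,
                    stringsAsFactors = FALSE)
                ## secondary placements for multimappers (vectorized)
                extra <- which(nh > 1L)
                if (length(extra)) {
                    nsec <- nh[extra] - 1L
                    eidx <- rep(extra, nsec)
                    total <- length(eidx)
                    w <- re[eidx] - rs[eidx]
                    ch <- sample(names(chromLengths), total, replace = TRUE,
                                 prob = chromLengths / sum(chromLengths))
                    st <- floor(runif(total) * (chromLengths[ch] - w))
                    rows[[length(rows) + 1L]] <- data.frame(
                        read_id = ids[eidx], library_id = libs[j],
                        chrom = ch, start = as.integer(st),
                        end = as.integer(st + w),
                        strand = srcStrand[i], n_alignments = nh[eidx],
                        locus = locusIds[i], primary = FALSE,
                        stringsAsFactors = FALSE)
                }
            }
            ## background reads
            nbg <- rpois(1, config@backgroundPerKb * sum(chromLengths) / 1000)
            if (nbg > 0L) {
                w <- sample(18:24, nbg, replace = TRUE)
                ch <- sample(names(chromLengths), nbg, replace = TRUE,
                             prob = chromLengths / sum(chromLengths))
                st <- vapply(seq_len(nbg), function(k)
                    sample.int(chromLengths[[ch[k]]] - w[k], 1L) - 1L,
                    integer(1))
                nh <- ifelse(runif(nbg) < 0.1,
                             sample(2:8, nbg, replace = TRUE), 1L)
                ids <- sprintf("r%08d", readCounter + seq_len(nbg))
                readCounter <- readCounter + nbg
                rows[[length(rows) + 1L]] <- data.frame(
                    read_id = ids, library_id = libs[j],
                    chrom = ch, start = st, end = st + w,
                    strand = sample(c("+", "-"), nbg, replace = TRUE),
                    n_alignments = as.integer(nh), locus = NA_character_,
                    primary = TRUE, stringsAsFactors = FALSE)
            }
        }
        readDf <- if (length(rows)) do.call(rbind, rows) else
            data.frame(read_id = character(0), library_id = character(0),
                       chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       n_alignments = integer(0), locus = character(0),
                       primary = logical(0))
        reads <- GenomicRanges::GRanges(
            readDf$chrom,
            IRanges::IRanges(start = readDf$start + 1L, end = readDf$end),
            strand = readDf$strand, seqlengths = chromLengths)
        if (nrow(readDf)) {
            chrStrings <- setNames(as.character(genome), names(genome))
            seqs <- substring(chrStrings[readDf$chrom],
                              readDf$start + 1L, readDf$end)
        } else seqs <- character(0)
        S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
            read_id = readDf$read_id, library_id = readDf$library_id,
            seq = unname(seqs), n_alignments = readDf$n_alignments,
            locus = readDf$locus, primary = readDf$primary)

        new("MirSimulation", genome = genome, reads = reads,
            precursors = precursors, decoys = decoys,
            trueCounts = counts, trueMeans = trueMeans,
            sizeFactors = sf, design = design, config = config)
    })
}

#' Run the full synthetic-experiment generator
#'
#' Convenience wrapper: \code{\link{generateGenome}} then
#' \code{\link{plantPrecursors}} then \code{\link{simulateLibraries}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MirSimulation}.
#' @examples
#' sim <- simulateMirnaExperiment(simulationConfig(
#'     seed = 7, nPrecursors = 3L, conditions = c(H = 2L, OC = 2L),
#'     nDecoyNcrna = 2L, nDecoyExpressed = 2L, backgroundPerKb = 0.2,
#'     meanRange = c(20, 50), chromLengths = c(chr1 = 5000L)))
#' sim
#' @export
simulateMirnaExperiment <- function(config) {
    genome <- generateGenome(config)
    truth <- plantPrecursors(genome, config)
    simulateLibraries(truth$genome, truth, config)
}
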