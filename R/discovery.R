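## Hairpin discovery around coverage islands: dual precursor-window
## excision, folding + hairpin topology, annotation against known miRNAs,
## cross-species precursor alignment, and the novel-miRNA classification
## filters (size, abundance, folding energy).

#' Excise the two candidate precursor windows around an island
#'
#' For every island two genomic windows are cut, anchored on the island
#' boundaries: \code{[start - 10, end + 50)} simulating the island as the
#' 5p arm, and \code{[start - 50, end + 10)} simulating it as the 3p arm
#' (coordinates 0-based half-open; extensions are clamped at chromosome
#' bounds). Minus-strand islands yield reverse-complemented sequences with
#' the two window roles swapped.
#'
#' @param islands \code{GRanges} of islands (strand used for orientation;
#'   \code{*} is treated as \code{+}).
#' @param genome \code{DNAStringSet} containing every island chromosome.
#' @param up,down short and long extensions in nt (defaults 10 and 50).
#' @return \code{GRanges} with two rows per island: columns \code{island}
#'   (name), \code{window_kind} (\code{"5p-sim"}/\code{"3p-sim"}) and
#'   \code{sequence} (strand-oriented).
#' @export
exciseWindows <- function(islands, genome, up = 10L, down = 50L) {
    miss <- setdiff(unique(as.character(GenomicRanges::seqnames(islands))),
                    names(genome))
    if (length(miss))
        stop("island chromosome(s) absent from genome: ",
             paste(miss, collapse = ", "))
    chrStrings <- setNames(as.character(genome), names(genome))
    chromLen <- setNames(nchar(chrStrings), names(chrStrings))
    n <- length(islands)
    ids <- if (!is.null(names(islands))) names(islands) else
        sprintf("island_%05d", seq_len(n))
    rows <- vector("list", n)
    for (k in seq_len(n)) {
        chrom <- as.character(GenomicRanges::seqnames(islands))[k]
        s0 <- GenomicRanges::start(islands)[k] - 1L
        e0 <- GenomicRanges::end(islands)[k]
        strand <- as.character(GenomicRanges::strand(islands))[k]
        if (strand == "*") strand <- "+"
        aS <- max(0L, s0 - up);   aE <- min(chromLen[[chrom]], e0 + down)
        bS <- max(0L, s0 - down); bE <- min(chromLen[[chrom]], e0 + up)
        seqA <- substring(chrStrings[[chrom]], aS + 1L, aE)
        seqB <- substring(chrStrings[[chrom]], bS + 1L, bE)
        if (strand == "-") {
            seqA <- .revcompChr(seqA)
            seqB <- .revcompChr(seqB)
            kinds <- c("3p-sim", "5p-sim")
        } else kinds <- c("5p-sim", "3p-sim")
        rows[[k]] <- data.frame(
            chrom = chrom, start = c(aS, bS), end = c(aE, bE),
            strand = strand, island = ids[k], window_kind = kinds,
            sequence = c(seqA, seqB), stringsAsFactors = FALSE)
    }
    df <- if (n) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   island = character(0), window_kind = character(0),
                   sequence = character(0))
    gr <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end),
        strand = df$strand, seqlengths = chromLen)
    gr$island <- df$island
    gr$window_kind <- df$window_kind
    gr$sequence <- df$sequence
    gr
}

#' Annotate islands against known miRNA intervals
#'
#' An island receives the name of any overlapping (>= 1 bp, strand-blind)
#' annotation of feature class \code{"miRNA"}; when several overlap, the
#' annotation whose midpoint is nearest the island midpoint wins.
#'
#' @param islands \code{GRanges}.
#' @param annotations \code{GRanges} with \code{feature_class} and
#'   \code{name} columns.
#' @return character vector of annotation names, \code{NA} where no miRNA
#'   annotation overlaps (novel candidates).
#' @export
annotateKnown <- function(islands, annotations) {
    out <- rep(NA_character_, length(islands))
    if (!length(annotations) || !length(islands)) return(out)
    mir <- annotations[annotations$feature_class == "miRNA"]
    if (!length(mir)) return(out)
    hits <- GenomicRanges::findOverlaps(islands, mir, ignore.strand = TRUE)
    if (!length(hits)) return(out)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    midI <- (GenomicRanges::start(islands)[q] +
                 GenomicRanges::end(islands)[q]) / 2
    midA <- (GenomicRanges::start(mir)[s] + GenomicRanges::end(mir)[s]) / 2
    d <- abs(midI - midA)
    o <- order(q, d, s)
    q <- q[o]; s <- s[o]
    first <- !duplicated(q)
    out[q[first]] <- mir$name[s[first]]
    out
}

#' Local alignment score of a precursor against a target sequence
#'
#' Smith-Waterman local alignment with affine gaps: match +1,
#' mismatch -2, a gap of length L costs 5 + 2*(L - 1) under the defaults.
#' The raw score is converted to a bit score
#' \code{(lambda * S - log(K)) / log(2)}; a hit is conserved when the bit
#' score exceeds \code{minBitScore}.
#'
#' @param query,target non-empty nucleotide strings.
#' @param match,mismatch match reward and mismatch penalty.
#' @param gapOpen,gapExtend gap costs (negative; a length-L gap scores
#'   \code{gapOpen + gapExtend * (L - 1)}).
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme.
#' @param minBitScore conservation cutoff (exclusive; default 90).
#' @return list with \code{score} (raw Smith-Waterman score),
#'   \code{bit_score} and \code{conserved} (logical).
#' @export
alignPrecursor <- function(query, target, match = 1, mismatch = -2,
                           gapOpen = -5, gapExtend = -2,
                           lambda = 1.28, K = 0.46, minBitScore = 90) {
    if (!nzchar(query) || !nzchar(target))
        stop("'query' and 'target' must be non-empty")
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = TRUE)
    ## Biostrings charges gapOpening + gapExtension for the first gap base
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(chartr("Uu", "Tt", query)),
        Biostrings::DNAString(chartr("Uu", "Tt", target)),
        type = "local", substitutionMatrix = mat,
        gapOpening = abs(gapOpen) - abs(gapExtend),
        gapExtension = abs(gapExtend))
    s <- Biostrings::score(pa)
    bits <- bitScore(s, lambda = lambda, K = K)
    list(score = s, bit_score = bits, conserved = bits > minBitScore)
}

#' Convert a raw alignment score to a bit score
#'
#' @param score raw local alignment score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return bit score \code{(lambda * score - log(K)) / log(2)}.
#' @export
bitScore <- function(score, lambda = 1.28, K = 0.46) {
    (lambda * score - log(K)) / log(2)
}

#' Classify a folded candidate as a novel miRNA
#'
#' Applies the novel-miRNA filters: mature size within
#' \code{sizeRange} (17-29 nt), a count of at least \code{minCount}
#' (1000) in at least one experimental library, folding energy strictly
#' below \code{mfeThreshold} (-20 kcal/mol), and a hairpin secondary
#' structure. The mature size is the modal read length of the island.
#'
#' @param mfe folding energy of the candidate (kcal/mol).
#' @param hairpin logical; hairpin topology of the candidate structure.
#' @param matureLen modal read length of the island (nt).
#' @param libCounts per-library counts for the island.
#' @param mfeThreshold,minCount,sizeRange filter settings.
#' @return one-row \code{DataFrame} with \code{status}
#'   (\code{"novel"}/\code{"rejected"}) and logical flags \code{size_ok},
#'   \code{count_ok}, \code{energy_ok}, \code{hairpin_ok}.
#' @export
classifyNovel <- function(mfe, hairpin, matureLen, libCounts,
                          mfeThreshold = -20, minCount = 1000L,
                          sizeRange = c(17L, 29L)) {
    sizeOk <- !is.na(matureLen) &&
        matureLen >= sizeRange[1] && matureLen <= sizeRange[2]
    countOk <- length(libCounts) > 0 && max(libCounts) >= minCount
    energyOk <- mfe < mfeThreshold
    hairpinOk <- isTRUE(hairpin)
    S4Vectors::DataFrame(
        status = if (sizeOk && countOk && energyOk && hairpinOk)
            "novel" else "rejected",
        size_ok = sizeOk, count_ok = countOk, energy_ok = energyOk,
        hairpin_ok = hairpinOk)
}

#' Discover known and novel miRNAs from a count experiment
#'
#' For every island: excise both precursor windows, fold each, take the
#' window of lower folding energy as the candidate, test its hairpin
#' topology, annotate against known miRNA intervals, and classify
#' unannotated candidates through the novel-miRNA filters.
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countReads}}.
#' @param genome \code{DNAStringSet}.
#' @param annotations optional \code{GRanges} of known annotations
#'   (feature class \code{"miRNA"} intervals are used).
#' @param params an \linkS4class{EnergyParams}.
#' @param mfeThreshold,minCount,sizeRange,minPairs filter settings (see
#'   \code{\link{classifyNovel}} and \code{\link{isHairpin}}).
#' @return \code{DataFrame}, one row per island: coordinates, chosen
#'   window kind, \code{mfe}, \code{structure}, \code{hairpin},
#'   \code{known_name}, \code{status} (\code{"known"}, \code{"novel"} or
#'   \code{"rejected"}) and the filter flags.
#' @export
discoverMirnas <- function(se, genome, annotations = NULL,
                           params = defaultEnergyParams(),
                           mfeThreshold = -20, minCount = 1000L,
                           sizeRange = c(17L, 29L), minPairs = 15L) {
    islands <- SummarizedExperiment::rowRanges(se)
    counts <- SummarizedExperiment::assay(se, "counts")
    windows <- exciseWindows(islands, genome)
    n <- length(islands)
    known <- if (!is.null(annotations))
        annotateKnown(islands, annotations) else rep(NA_character_, n)
    res <- vector("list", n)
    ids <- names(islands)
    for (k in seq_len(n)) {
        w <- windows[windows$island == ids[k]]
        folds <- lapply(w$sequence, foldMfe, params = params)
        mfes <- vapply(folds, `[[`, numeric(1), "mfe")
        best <- which.min(mfes)
        structure <- folds[[best]]$structure
        hp <- isHairpin(structure, minPairs = minPairs)
        cls <- classifyNovel(mfes[best], hp,
                             islands$modal_read_len[k], counts[k, ],
                             mfeThreshold = mfeThreshold,
                             minCount = minCount, sizeRange = sizeRange)
        status <- if (!is.na(known[k])) "known" else cls$status
        res[[k]] <- S4Vectors::DataFrame(
            island = ids[k],
            chrom = as.character(GenomicRanges::seqnames(islands))[k],
            start = GenomicRanges::start(islands)[k] - 1L,
            end = GenomicRanges::end(islands)[k],
            strand = as.character(GenomicRanges::strand(islands))[k],
            window_kind = w$window_kind[best],
            mfe = mfes[best], structure = structure, hairpin = hp,
            known_name = known[k], status = status,
            size_ok = cls$size_ok, count_ok = cls$count_ok,
            energy_ok = cls$energy_ok, hairpin_ok = cls$hairpin_ok)
    }
    if (n) do.call(rbind, res) else
        S4Vectors::DataFrame(island = character(0))
}
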