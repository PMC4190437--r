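## Locus detection and quantification: per-base coverage pooled over
## libraries, maximal covered runs ("coverage islands") filtered on peak
## depth, and per-island per-library read counting into a
## SummarizedExperiment.

#' Compute per-base read coverage
#'
#' Depth at each position is the number of retained read placements
#' covering it, pooled over all libraries and both strands.
#'
#' @param reads \code{GRanges} of read placements (seqlengths set).
#' @param seqlengths optional named vector overriding the seqlengths
#'   carried by \code{reads}.
#' @return \code{RleList} of per-chromosome depth vectors.
#' @export
computeCoverage <- function(reads, seqlengths = NULL) {
    if (is.null(seqlengths))
        seqlengths <- GenomeInfoDb::seqlengths(reads)
    if (any(is.na(seqlengths)))
        stop("seqlengths must be known to compute coverage")
    bad <- GenomicRanges::end(reads) >
        seqlengths[as.character(GenomicRanges::seqnames(reads))]
    if (any(bad))
        stop(sum(bad), " read(s) extend beyond the chromosome end")
    GenomicRanges::coverage(reads, width = as.list(seqlengths))
}

#' Detect coverage islands
#'
#' Islands are maximal runs of positions with depth >= 1; only islands
#' whose peak depth reaches \code{minPeak} (default 3, i.e. genomic
#' coverage greater than 2) are retained, in coordinate order.
#'
#' @param cov \code{RleList} from \code{\link{computeCoverage}}.
#' @param minPeak minimal peak depth for retention.
#' @return \code{GRanges} of islands with a \code{peak_coverage} column.
#' @export
detectIslands <- function(cov, minPeak = 3L) {
    sl <- vapply(cov, length, integer(1))
    res <- lapply(names(cov), function(chrom) {
        v <- IRanges::slice(cov[[chrom]], lower = 1L)
        if (!length(v)) {
            g0 <- GenomicRanges::GRanges(seqlengths = sl)
            g0$peak_coverage <- integer(0)
            return(g0)
        }
        peak <- IRanges::viewMaxs(v)
        r <- IRanges::ranges(v)[peak >= minPeak]
        peak <- peak[peak >= minPeak]
        gr <- GenomicRanges::GRanges(rep(chrom, length(r)), r,
                                     strand = rep("*", length(r)),
                                     seqlengths = sl)
        gr$peak_coverage <- as.integer(peak)
        gr
    })
    out <- suppressWarnings(do.call(c, res))
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
    if (length(out)) names(out) <- sprintf("island_%05d", seq_along(out))
    out
}

#' Count reads per island per library
#'
#' A read placement is assigned to an island when at least
#' \code{minOverlapFrac} of the read's bases lie inside it; every read is
#' counted at most once (its single retained placement, and the island of
#' largest overlap should several qualify). Islands also record the modal
#' read length and the majority strand of their assigned reads, used
#' downstream as the mature-arm proxy and excision orientation.
#'
#' @param islands \code{GRanges} of non-overlapping islands.
#' @param reads \code{GRanges} of read placements (one per read, i.e.
#'   after \code{\link{filterMultimappers}}) with a \code{library_id}
#'   column.
#' @param design \code{DataFrame} or data.frame with columns
#'   \code{library_id}, \code{tissue}, \code{condition}.
#' @param minOverlapFrac minimal fraction of read bases inside the island
#'   (default 0.5).
#' @return A \code{SummarizedExperiment}: assay \code{"counts"}
#'   (islands x libraries integer matrix), \code{rowRanges} = islands
#'   (augmented with \code{modal_read_len} and majority strand),
#'   \code{colData} = design.
#' @export
countReads <- function(islands, reads, design, minOverlapFrac = 0.5) {
    design <- S4Vectors::DataFrame(design)
    libs <- as.character(design$library_id)
    if (length(reads)) {
        unknown <- setdiff(unique(reads$library_id), libs)
        if (length(unknown))
            stop("library absent from design table: ",
                 paste(unknown, collapse = ", "))
    }
    counts <- matrix(0L, length(islands), length(libs),
                     dimnames = list(names(islands), libs))
    modalLen <- rep(NA_integer_, length(islands))
    majStrand <- rep("*", length(islands))
    if (length(reads) && length(islands)) {
        hits <- GenomicRanges::findOverlaps(reads, islands,
                                            ignore.strand = TRUE)
        if (length(hits)) {
            ovw <- GenomicRanges::width(IRanges::pintersect(
                GenomicRanges::granges(reads)[S4Vectors::queryHits(hits)],
                GenomicRanges::granges(islands)[S4Vectors::subjectHits(hits)],
                ignore.strand = TRUE))
            frac <- ovw / GenomicRanges::width(reads)[
                S4Vectors::queryHits(hits)]
            ok <- frac >= minOverlapFrac
            q <- S4Vectors::queryHits(hits)[ok]
            s <- S4Vectors::subjectHits(hits)[ok]
            f <- frac[ok]
            ## one island per read: keep the largest-overlap assignment
            o <- order(q, -f, s)
            q <- q[o]; s <- s[o]
            first <- !duplicated(q)
            q <- q[first]; s <- s[first]
            lib <- factor(reads$library_id[q], levels = libs)
            tab <- table(factor(s, levels = seq_along(islands)), lib)
            counts <- matrix(as.integer(tab), nrow = length(islands),
                             dimnames = list(names(islands), libs))
            rl <- GenomicRanges::width(reads)[q]
            rs <- as.character(GenomicRanges::strand(reads))[q]
            for (i in unique(s)) {
                sel <- s == i
                tl <- table(rl[sel])
                modalLen[i] <- as.integer(names(tl)[which.max(tl)])
                ts <- table(rs[sel])
                majStrand[i] <- names(ts)[which.max(ts)]
            }
        }
    }
    islands$modal_read_len <- modalLen
    strand_known <- majStrand %in% c("+", "-")
    GenomicRanges::strand(islands)[strand_known] <-
        majStrand[strand_known]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = islands,
        colData = design)
}
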