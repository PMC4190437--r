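## Read-level filters applied before locus detection: adaptor trimming
## with size selection, multimapper removal, and exclusion of reads
## overlapping annotated non-miRNA ncRNAs. All filters are idempotent and
## never modify a read except by trimming.

#' Trim 3' adaptors and apply size selection
#'
#' For each read the adaptor is searched at every start position; a
#' position qualifies when the overlap between adaptor and read (a partial,
#' 3'-overhanging match is allowed) is at least \code{minOverlap} nt and
#' the number of mismatches over that overlap is at most
#' \code{min(maxMismatch, overlap \%/\% 3)} -- the mismatch budget is
#' scaled down for short partial matches so that chance matches at the
#' read end do not clip adaptor-free reads. The leftmost qualifying
#' position is the trim point; bases from there on are removed. Reads
#' whose remaining insert falls outside \code{[minLen, maxLen]} are
#' discarded; untrimmed reads within that range are retained.
#'
#' @param sequences character vector (or \code{DNAStringSet}) of raw reads.
#' @param adaptor adaptor sequence (non-empty).
#' @param maxMismatch maximal mismatches over a full-length match
#'   (default 2).
#' @param minLen,maxLen retained insert size range (defaults 17 and 26 nt).
#' @param minOverlap minimal adaptor overlap to accept a match (default 3).
#' @return named character vector of retained (possibly trimmed) reads;
#'   names follow the input names.
#' @examples
#' trimReads(c(r1 = paste0(strrep("A", 20), "TGGAATTCTCGG")),
#'           adaptor = "TGGAATTCTCGGGTGCCAAGG")
#' @export
trimReads <- function(sequences, adaptor, maxMismatch = 2L,
                      minLen = 17L, maxLen = 26L, minOverlap = 3L) {
    if (missing(adaptor) || !nzchar(adaptor))
        stop("'adaptor' must be a non-empty sequence")
    if (minLen > maxLen) stop("'minLen' must be <= 'maxLen'")
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
    advec <- strsplit(toupper(adaptor), "", fixed = TRUE)[[1]]
    alen <- length(advec)
    trimOne <- function(s) {
        v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
        n <- length(v)
        for (p in seq_len(n)) {
            ov <- min(alen, n - p + 1L)
            if (ov < minOverlap) break
            mm <- sum(v[p:(p + ov - 1L)] != advec[seq_len(ov)])
            if (mm <= min(maxMismatch, ov %/% 3L))
                return(substr(s, 1L, p - 1L))
        }
        s
    }
    trimmed <- vapply(sequences, trimOne, character(1))
    names(trimmed) <- names(sequences)
    keep <- nchar(trimmed) >= minLen & nchar(trimmed) <= maxLen
    trimmed[keep]
}

#' Remove multimapping reads and collapse retained ones to one placement
#'
#' Reads whose total alignment count exceeds \code{maxHits} are removed
#' entirely. Retained multimapped reads contribute a single counting
#' placement: their best alignment, taken as the first placement in the
#' input's best-to-worst order (ties resolved towards the lowest
#' coordinate by that ordering).
#'
#' @param reads \code{GRanges} with metadata columns \code{read_id} and
#'   \code{n_alignments} (one row per placement, best placement first).
#' @param maxHits maximal tolerated alignment count (default 6; reads with
#'   more alignments are dropped, reads with exactly \code{maxHits} kept).
#' @return filtered \code{GRanges}, one placement per retained read.
#' @export
filterMultimappers <- function(reads, maxHits = 6L) {
    nh <- reads$n_alignments
    if (is.null(nh) || anyNA(nh)) {
        bad <- if (is.null(nh)) "all reads" else
            paste(head(reads$read_id[is.na(nh)], 3L), collapse = ", ")
        stop("missing alignment count for: ", bad)
    }
    reads <- reads[nh <= maxHits]
    if (!length(reads)) return(reads)
    reads[!duplicated(paste(reads$library_id, reads$read_id))]
}

#' Discard reads overlapping annotated non-miRNA ncRNAs
#'
#' A read is removed when it overlaps, by at least one base on the same
#' chromosome, any annotation interval of feature class \code{"ncRNA"}.
#' Overlaps with \code{"miRNA"} annotations never cause removal. The
#' comparison is strand-blind by default.
#'
#' @param reads \code{GRanges} of read placements.
#' @param annotations \code{GRanges} with a \code{feature_class} column
#'   (\code{"miRNA"} or \code{"ncRNA"}); may be empty.
#' @param sameStrand require matching strand for removal (default FALSE).
#' @return filtered \code{GRanges}.
#' @export
removeNcrnaOverlaps <- function(reads, annotations, sameStrand = FALSE) {
    if (length(annotations) == 0L) return(reads)
    if (is.null(annotations$feature_class))
        stop("'annotations' must carry a 'feature_class' column")
    nc <- annotations[annotations$feature_class == "ncRNA"]
    if (!length(nc)) return(reads)
    hits <- GenomicRanges::findOverlaps(reads, nc,
                                        ignore.strand = !sameStrand)
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) reads[-drop] else reads
}
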