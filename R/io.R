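## File-format interfaces. FASTA via Biostrings, GFF3 via rtracklayer,
## SAM reading via Rsamtools; SAM writing is plain record formatting
## (header @SQ lines, NH tag for the alignment count).

#' Write aligned reads as a SAM file
#'
#' Emits a minimal single-end SAM: \code{@HD}/\code{@SQ} header, flag 0/16
#' by strand, MAPQ 255, full-length match CIGAR, and an \code{NH:i:} tag
#' carrying the read's total alignment count. Sequences are stored on the
#' forward genomic strand.
#'
#' @param reads \code{GRanges} with metadata columns \code{read_id},
#'   \code{seq}, \code{n_alignments}; seqlengths must be set.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(reads, path) {
    sl <- GenomeInfoDb::seqlengths(reads)
    if (any(is.na(sl))) stop("reads must carry seqlengths")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    if (length(reads)) {
        flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                       16L, 0L)
        w <- GenomicRanges::width(reads)
        rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                       reads$read_id, flag,
                       as.character(GenomicRanges::seqnames(reads)),
                       GenomicRanges::start(reads), w, reads$seq,
                       reads$n_alignments)
    } else rec <- character(0)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read aligned small-RNA reads from a SAM/BAM file
#'
#' Parses alignments via Rsamtools (SAM input is converted on the fly) into
#' the \code{GRanges} representation used throughout the package, taking
#' the total alignment count from the \code{NH} tag.
#'
#' @param path SAM or BAM file.
#' @param library_id library label attached to every read.
#' @return \code{GRanges} with metadata columns \code{read_id},
#'   \code{library_id}, \code{seq}, \code{n_alignments}.
#' @export
readSmallRnaSam <- function(path, library_id) {
    bam <- path
    if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, destination = dest,
                                overwrite = TRUE, indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "qwidth", "strand", "seq"),
        tag = "NH")
    x <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(x$pos)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    nh <- x$tag$NH[keep]
    nh[is.na(nh)] <- 1L
    gr <- GenomicRanges::GRanges(
        as.character(x$rname[keep]),
        IRanges::IRanges(start = x$pos[keep], width = x$qwidth[keep]),
        strand = x$strand[keep],
        seqlengths = hdr)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        read_id = x$qname[keep], library_id = library_id,
        seq = as.character(x$seq)[keep], n_alignments = as.integer(nh))
    gr
}

#' Read annotation intervals from a GFF3 file
#'
#' Imports a GFF3 (1-based, inclusive) and maps its feature types onto the
#' two-class vocabulary used by the read filters: type \code{miRNA} becomes
#' feature class \code{"miRNA"}, everything else \code{"ncRNA"}.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} with metadata columns \code{feature_class} and
#'   \code{name}.
#' @export
readAnnotationGff <- function(path) {
    g <- rtracklayer::import(path, format = "GFF3")
    cls <- ifelse(as.character(g$type) == "miRNA", "miRNA", "ncRNA")
    nm <- if (!is.null(g$Name)) as.character(g$Name) else
        if (!is.null(g$ID)) as.character(g$ID) else
            paste0("feature_", seq_along(g))
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(feature_class = cls,
                                                name = nm)
    g
}

#' Write annotation intervals as GFF3
#'
#' @param gr \code{GRanges} with \code{feature_class} and \code{name}
#'   metadata columns (feature class is written as the GFF3 type).
#' @param path output file path.
#' @param source source field for column 2.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGff <- function(gr, path, source = "mirIsland") {
    out <- gr
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        source = source, type = gr$feature_class, Name = gr$name)
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}

#' Write coverage islands as BED6
#'
#' @param islands \code{GRanges} with a \code{peak_coverage} column.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeIslandsBed <- function(islands, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(islands)),
        start = GenomicRanges::start(islands) - 1L,
        end = GenomicRanges::end(islands),
        name = if (!is.null(names(islands))) names(islands) else
            sprintf("island_%05d", seq_along(islands)),
        score = islands$peak_coverage,
        strand = as.character(GenomicRanges::strand(islands)))
    df$strand[df$strand == "*"] <- "."
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a synthetic experiment to disk
#'
#' Produces, under \code{dir}: \code{genome.fa}; one SAM file per library
#' (\code{<library_id>.sam}); \code{annotations.gff3} with the planted
#' precursors as \code{miRNA} features and the decoy ncRNA loci as
#' \code{ncRNA} features; \code{truth.tsv} (planted loci with coordinates,
#' DE flags and fold changes); \code{true_counts.tsv};
#' \code{size_factors.tsv}; and \code{design.tsv}
#' (\code{library_id}, \code{tissue}, \code{condition}).
#'
#' @param sim a \linkS4class{MirSimulation}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(simGenome(sim), file.path(dir, "genome.fa"))
    design <- simDesign(sim)
    reads <- simReads(sim)
    for (lib in design$library_id)
        writeSam(reads[reads$library_id == lib],
                 file.path(dir, paste0(lib, ".sam")))
    prec <- simPrecursors(sim)
    ann <- c(GenomicRanges::granges(prec),
             GenomicRanges::granges(simDecoys(sim)[
                 simDecoys(sim)$feature_class == "ncRNA"]))
    ann$feature_class <- c(rep("miRNA", length(prec)),
                           rep("ncRNA", sum(simDecoys(sim)$feature_class ==
                                                "ncRNA")))
    ann$name <- c(names(prec),
                  names(simDecoys(sim))[simDecoys(sim)$feature_class ==
                                            "ncRNA"])
    writeAnnotationGff(ann, file.path(dir, "annotations.gff3"))
    truthDf <- as.data.frame(prec)
    truthDf <- cbind(locus = names(prec), truthDf)
    write.table(truthDf, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(simTrueCounts(sim)),
                file.path(dir, "true_counts.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    write.table(data.frame(library_id = names(simSizeFactors(sim)),
                           size_factor = simSizeFactors(sim)),
                file.path(dir, "size_factors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(design), file.path(dir, "design.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
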