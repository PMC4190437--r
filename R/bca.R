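## Between-class analysis: a principal component analysis of the table of
## group means, weighted by group size, maximizing between-group variance.
## Input counts are transformed to log2(normalized + 1) and centered per
## locus before the group-mean table is built.

#' Between-class analysis of a count experiment
#'
#' Normalizes counts by median-of-ratios size factors, transforms to
#' \code{log2(x + 1)}, centers each locus, builds the groups x loci table
#' of group means (weighted-centered), and eigen-decomposes its
#' group-size-weighted covariance. Samples are projected onto the
#' loadings; a \code{g}-group design yields at most \code{g - 1}
#' non-degenerate axes.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay and a
#'   \code{condition} column, or a count matrix (then supply
#'   \code{groups}).
#' @param groups per-library group labels (ignored when \code{se} carries
#'   a \code{condition} column).
#' @param nAxes number of axes to retain (default: all non-degenerate).
#' @param transform function applied to normalized counts before
#'   centering (default \code{log2(x + 1)}); use \code{identity} for
#'   pre-transformed input.
#' @return A \linkS4class{BCAResult}.
#' @export
runBCA <- function(se, groups = NULL, nAxes = NULL,
                   transform = function(x) log2(x + 1)) {
    if (is(se, "SummarizedExperiment")) {
        counts <- SummarizedExperiment::assay(se, "counts")
        groups <- as.character(SummarizedExperiment::colData(se)$condition)
    } else counts <- as.matrix(se)
    if (is.null(groups))
        stop("'groups' required when 'se' is a matrix")
    groups <- factor(groups)
    if (nlevels(groups) < 2)
        stop("between-class analysis needs at least two groups")
    sf <- medianRatioSizeFactors(counts)
    x <- transform(sweep(counts, 2, sf, "/"))
    x <- t(x - rowMeans(x))                       # samples x loci, centered
    n <- nrow(x)
    G <- do.call(rbind, lapply(levels(groups), function(g)
        colMeans(x[groups == g, , drop = FALSE])))
    rownames(G) <- levels(groups)
    w <- as.numeric(table(groups)) / n
    Gc <- sweep(G, 2, colSums(G * w))             # weighted-centered means
    sv <- svd(Gc * sqrt(w))
    maxAxes <- max(0L, min(nlevels(groups) - 1L, sum(sv$d > 1e-10)))
    if (is.null(nAxes)) nAxes <- maxAxes
    nAxes <- min(nAxes, maxAxes)
    idx <- seq_len(nAxes)
    ev <- sv$d^2
    loadings <- sv$v[, idx, drop = FALSE]
    dimnames(loadings) <- list(colnames(x), paste0("Axis", idx))
    scores <- x %*% loadings
    rownames(scores) <- colnames(counts)
    groupScores <- Gc %*% loadings
    new("BCAResult",
        loadings = loadings,
        scores = scores,
        groupScores = groupScores,
        eigenvalues = ev[idx],
        varProp = if (length(idx) && sum(ev[idx]) > 0)
            ev[idx] / sum(ev[idx]) else numeric(0),
        groups = groups)
}
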