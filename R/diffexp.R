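## Differential expression of locus counts between two condition groups:
## median-of-ratios size factors, gene-wise method-of-moments dispersions
## with a 1/mean trend and maximum sharing, a negative-binomial
## conditional exact test on replicate-group sums, and Benjamini-Hochberg
## adjustment.

#' Median-of-ratios library size factors
#'
#' For library j the size factor is the median, over loci whose counts are
#' positive in every library, of the ratio between the locus count in j
#' and the locus geometric mean across libraries.
#'
#' @param counts integer matrix, loci x libraries.
#' @return named numeric vector of positive size factors.
#' @examples
#' m <- matrix(c(10, 20, 40, 30, 60, 120), ncol = 2)
#' medianRatioSizeFactors(m)  # second library twice as deep
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts <= 0) == 0
    if (!any(allPos))
        stop("no locus has positive counts in every library; ",
             "add a pseudo-count or drop empty libraries")
    logc <- log(counts[allPos, , drop = FALSE])
    logGeo <- rowMeans(logc)
    sf <- apply(logc, 2, function(x) exp(median(x - logGeo)))
    if (is.null(names(sf)) && !is.null(colnames(counts)))
        names(sf) <- colnames(counts)
    sf
}

#' Gene-wise method-of-moments dispersions with a 1/mean trend
#'
#' On normalized counts, each locus gets the method-of-moments estimate
#' \code{alpha = max(0, (v - m) / m^2)}, where \code{m} is the mean over
#' all samples and \code{v} the within-group pooled variance. A
#' mean-dispersion trend \code{a0 + a1/m} is then fitted across loci with
#' positive estimates, and the working dispersion of each locus is the
#' maximum of its gene-wise estimate and the trend value at its mean
#' (conservative sharing).
#'
#' @param counts integer matrix, loci x libraries.
#' @param sizeFactors named numeric vector of library size factors.
#' @param groups factor (or coercible) of library group labels; at least
#'   one group needs two or more replicates.
#' @return list with \code{dispersion} (working values, used by the
#'   test), \code{dispGene} (raw gene-wise estimates), \code{dispFit}
#'   (trend values) and \code{trendCoef}.
#' @export
momDispersions <- function(counts, sizeFactors, groups) {
    counts <- as.matrix(counts)
    groups <- factor(groups)
    sizes <- table(groups)
    if (all(sizes < 2))
        stop("no group has replicates; dispersions cannot be estimated")
    norm <- sweep(counts, 2, sizeFactors, "/")
    m <- rowMeans(norm)
    ## within-group pooled variance
    num <- rep(0, nrow(norm)); df <- 0
    for (g in levels(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2) next
        vg <- apply(norm[, idx, drop = FALSE], 1, var)
        num <- num + vg * (length(idx) - 1)
        df <- df + (length(idx) - 1)
    }
    v <- num / df
    dispGene <- pmax(0, (v - m) / m^2)
    dispGene[!is.finite(dispGene)] <- 0
    use <- which(dispGene > 0 & m > 0)
    a0 <- stats::median(dispGene[use])
    a1 <- 0
    if (length(use) >= 10) {
        fit <- try(lm(dispGene[use] ~ I(1 / m[use])), silent = TRUE)
        if (!inherits(fit, "try-error")) {
            cf <- coef(fit)
            if (is.finite(cf[1]) && cf[1] > 0) a0 <- unname(cf[1])
            if (is.finite(cf[2]) && cf[2] > 0) a1 <- unname(cf[2])
        }
    }
    if (!is.finite(a0) || a0 < 0) a0 <- 0
    dispFit <- a0 + a1 / pmax(m, 1e-8)
    working <- pmax(dispGene, dispFit)
    list(dispersion = working, dispGene = dispGene, dispFit = dispFit,
         trendCoef = c(a0 = a0, a1 = a1))
}

## pmf of the sum of a replicate group: NB with mean mu and variance
## mu + disp * q0^2 * sum(s_j^2) (exact moments for a sum of independent
## NB(q0 * s_j, disp) replicates); Poisson when disp = 0.
.groupSumPmf <- function(x, mu, varExtra) {
    if (varExtra <= 0) return(dpois(x, mu))
    size <- mu^2 / varExtra
    dnbinom(x, mu = mu, size = size)
}

#' Negative-binomial conditional exact test for one locus
#'
#' Conditions on the total count K over both groups: every split
#' \code{(a, K - a)} is enumerated, scored by the product of the two
#' group-sum NB laws (group mean \code{q0 * S_g} with
#' \code{q0 = K / (S_A + S_B)} and \code{S_g} the summed size factors;
#' group variance \code{mu_g + dispersion * q0^2 * sum(s_j^2)}, the exact
#' moments of a sum of independent NB replicates), and the p-value is the
#' total probability of splits no more likely than the observed one,
#' renormalized over all splits. With dispersion 0 the law degenerates to
#' a binomial split. The test is symmetric in the two groups.
#'
#' @param countsA,countsB integer count vectors of the two replicate
#'   groups.
#' @param sizeFactorsA,sizeFactorsB size factors of the corresponding
#'   libraries.
#' @param dispersion working NB dispersion (>= 0).
#' @return raw p-value in [0, 1].
#' @export
nbExactTest <- function(countsA, countsB, sizeFactorsA, sizeFactorsB,
                        dispersion) {
    if (any(c(countsA, countsB) %% 1 != 0) || any(c(countsA, countsB) < 0))
        stop("counts must be non-negative integers")
    if (dispersion < 0) stop("'dispersion' must be >= 0")
    kA <- sum(countsA); kB <- sum(countsB)
    K <- kA + kB
    if (K == 0) return(1)
    SA <- sum(sizeFactorsA); SB <- sum(sizeFactorsB)
    q0 <- K / (SA + SB)
    muA <- q0 * SA; muB <- q0 * SB
    vexA <- dispersion * q0^2 * sum(sizeFactorsA^2)
    vexB <- dispersion * q0^2 * sum(sizeFactorsB^2)
    a <- 0:K
    pr <- .groupSumPmf(a, muA, vexA) * .groupSumPmf(K - a, muB, vexB)
    tot <- sum(pr)
    if (tot <= 0) return(1)
    pobs <- pr[kA + 1]
    p <- sum(pr[pr <= pobs * (1 + 1e-8)]) / tot
    min(1, max(0, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted p-values are transformed to
#' \code{q_(i) = min_{j >= i} m * p_(j) / j}, capped at 1, and returned in
#' the original order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Differential expression between two condition groups
#'
#' Runs the whole per-locus pipeline on a count experiment: size factors
#' from the full matrix restricted to the contrasted libraries,
#' method-of-moments dispersions with trend sharing, the NB conditional
#' exact test, and BH adjustment. Loci with zero counts in both groups
#' are assigned p = 1 and excluded from the number of tests used by the
#' adjustment (their adjusted p is also 1).
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay and a
#'   \code{condition} column in \code{colData}, or a plain count matrix
#'   (then supply \code{conditions}).
#' @param contrast character of length 2: the two condition labels,
#'   fold changes reported as \code{contrast[2] / contrast[1]}.
#' @param conditions optional vector of per-library condition labels when
#'   \code{se} is a matrix.
#' @param dispersions optional precomputed working dispersions.
#' @return \code{DataFrame}: per-locus normalized group means, fold
#'   change, raw and BH-adjusted p-values and the dispersion used.
#' @export
runDiffExp <- function(se, contrast, conditions = NULL,
                       dispersions = NULL) {
    if (is(se, "SummarizedExperiment")) {
        counts <- SummarizedExperiment::assay(se, "counts")
        conditions <- as.character(SummarizedExperiment::colData(se)$condition)
    } else counts <- as.matrix(se)
    if (is.null(conditions))
        stop("'conditions' required when 'se' is a matrix")
    if (length(contrast) != 2 || !all(contrast %in% conditions))
        stop("'contrast' must name two condition labels present in the data")
    selA <- conditions == contrast[1]
    selB <- conditions == contrast[2]
    sub <- counts[, selA | selB, drop = FALSE]
    grp <- factor(conditions[selA | selB], levels = contrast)
    sf <- medianRatioSizeFactors(sub)
    if (is.null(dispersions))
        dispersions <- momDispersions(sub, sf, grp)$dispersion
    idxA <- which(grp == contrast[1])
    idxB <- which(grp == contrast[2])
    norm <- sweep(sub, 2, sf, "/")
    meanA <- rowMeans(norm[, idxA, drop = FALSE])
    meanB <- rowMeans(norm[, idxB, drop = FALSE])
    n <- nrow(sub)
    pval <- numeric(n)
    for (i in seq_len(n)) {
        pval[i] <- nbExactTest(sub[i, idxA], sub[i, idxB],
                               sf[idxA], sf[idxB], dispersions[i])
    }
    nonzero <- meanA + meanB > 0
    pval[!nonzero] <- 1
    padj <- rep(1, n)
    if (any(nonzero)) padj[nonzero] <- bhAdjust(pval[nonzero])
    S4Vectors::DataFrame(
        locus = if (!is.null(rownames(sub))) rownames(sub) else
            as.character(seq_len(n)),
        baseMeanA = meanA, baseMeanB = meanB,
        foldChange = ifelse(meanA > 0, meanB / meanA,
                            ifelse(meanB > 0, Inf, NA_real_)),
        pvalue = pval, padj = padj, dispersion = dispersions)
}
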