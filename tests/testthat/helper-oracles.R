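## Independent oracles used across the suite. Each reimplements the
## contract of an operation by direct enumeration or brute force, sharing
## no code path with the package implementation it checks.

## --- secondary structure -------------------------------------------------

## All pseudoknot-free structures of seq (character scalar) as lists of
## pair matrices, honouring pairability and the minimum loop size.
enumStructures <- function(seq, minLoop = 3L) {
    v <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
    ok <- function(a, b) paste0(v[a], v[b]) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG")
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) {
        if (i > j) return(list(matrix(integer(0), ncol = 2)))
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        out <- rec(i + 1L, j)  # i unpaired
        for (k in seq_len(j)) {
            if (k <= i + minLoop) next
            if (!ok(i, k)) next
            inner <- rec(i + 1L, k - 1L)
            outer <- rec(k + 1L, j)
            for (a in inner) for (b in outer)
                out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
        memo[[key]] <- out
        out
    }
    rec(1L, length(v))
}

pairsToDotBracket <- function(pairs, n) {
    s <- rep(".", n)
    if (nrow(pairs)) {
        s[pairs[, 1]] <- "("
        s[pairs[, 2]] <- ")"
    }
    paste(s, collapse = "")
}

## Exhaustive MFE: minimum structureEnergy over every enumerated structure.
oracleMfe <- function(seq, params = defaultEnergyParams()) {
    structs <- enumStructures(seq, minLoop = params@minLoop)
    n <- nchar(seq)
    min(vapply(structs, function(p)
        structureEnergy(seq, pairsToDotBracket(p, n), params), numeric(1)))
}

## Terminal-loop count by explicit stack simulation.
oracleTerminalLoops <- function(structure) {
    v <- strsplit(structure, "")[[1]]
    depth <- 0L; loops <- 0L; lastOpen <- FALSE
    for (ch in v) {
        if (ch == "(") { depth <- depth + 1L; lastOpen <- TRUE }
        else if (ch == ")") {
            if (lastOpen) loops <- loops + 1L
            depth <- depth - 1L
            lastOpen <- FALSE
        }
    }
    loops
}

## --- exact test ----------------------------------------------------------

## NB pmf written out via lgamma (no dnbinom), Poisson via lfactorial.
oracleSumPmf <- function(x, mu, varExtra) {
    if (varExtra <= 0) return(exp(-mu + x * log(mu) - lfactorial(x)))
    r <- mu^2 / varExtra          # size
    p <- r / (r + mu)
    exp(lgamma(x + r) - lgamma(r) - lfactorial(x) +
            r * log(p) + x * log1p(-p))
}

oracleExactTest <- function(countsA, countsB, sfA, sfB, disp) {
    kA <- sum(countsA); K <- kA + sum(countsB)
    if (K == 0) return(1)
    SA <- sum(sfA); SB <- sum(sfB)
    q0 <- K / (SA + SB)
    a <- 0:K
    pr <- oracleSumPmf(a, q0 * SA, disp * q0^2 * sum(sfA^2)) *
        oracleSumPmf(K - a, q0 * SB, disp * q0^2 * sum(sfB^2))
    sum(pr[pr <= pr[kA + 1] * (1 + 1e-8)]) / sum(pr)
}

## --- BH step-up ----------------------------------------------------------

oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    if (m > 1)
        for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## --- coverage / islands / counting --------------------------------------

## reads: data.frame with start, end (0-based half-open) on one chromosome
oracleCoverage <- function(starts, ends, len) {
    depth <- integer(len)
    for (k in seq_along(starts)) {
        idx <- (starts[k] + 1L):ends[k]
        depth[idx] <- depth[idx] + 1L
    }
    depth
}

## maximal runs of depth >= 1, retained when max depth >= minPeak
oracleIslands <- function(depth, minPeak = 3L) {
    runs <- list()
    i <- 1L; n <- length(depth)
    while (i <= n) {
        if (depth[i] >= 1L) {
            j <- i
            while (j < n && depth[j + 1L] >= 1L) j <- j + 1L
            if (max(depth[i:j]) >= minPeak)
                runs[[length(runs) + 1L]] <- c(start = i, end = j,
                                               peak = max(depth[i:j]))
            i <- j + 1L
        } else i <- i + 1L
    }
    if (length(runs)) do.call(rbind, runs) else
        matrix(integer(0), ncol = 3,
               dimnames = list(NULL, c("start", "end", "peak")))
}

## --- local alignment (Gotoh affine DP, independent of Biostrings) -------

oracleLocalAlign <- function(x, y, match = 1, mismatch = -2,
                             gapOpen = -5, gapExtend = -2) {
    a <- strsplit(toupper(x), "")[[1]]
    b <- strsplit(toupper(y), "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)   # gap in y (consume x)
    Iy <- matrix(NEG, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (a[i] == b[j]) match else mismatch
            M[i + 1, j + 1] <- max(0,
                                   M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
            Ix[i + 1, j + 1] <- max(M[i, j + 1] + gapOpen,
                                    Ix[i, j + 1] + gapExtend)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] + gapOpen,
                                    Iy[i + 1, j] + gapExtend)
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

## --- misc ----------------------------------------------------------------

revcomp <- function(x) {
    v <- rev(strsplit(toupper(x), "")[[1]])
    paste(chartr("ACGT", "TGCA", v), collapse = "")
}

## small GRanges of reads from a coordinate data.frame
readsGRanges <- function(df, seqlen = c(chr1 = 1000L)) {
    n <- nrow(df)
    gr <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end),
        strand = if (!is.null(df$strand)) df$strand else rep("+", n),
        seqlengths = seqlen)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        read_id = if (!is.null(df$read_id)) df$read_id else
            sprintf("r%03d", seq_len(n)),
        library_id = if (!is.null(df$library_id)) df$library_id else
            rep("L1", n),
        seq = strrep("A", df$end - df$start),
        n_alignments = if (!is.null(df$n_alignments)) df$n_alignments else
            rep(1L, n))
    gr
}
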