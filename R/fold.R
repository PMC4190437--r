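## RNA secondary-structure prediction: minimum free energy over
## pseudoknot-free structures under the package's simplified
## nearest-neighbor model (see ?energyParams). The O(n^3) dynamic program
## lives in src/fold.cpp; this file provides the user-facing wrapper, the
## explicit structure-scoring function (the model definition in one place),
## and the hairpin-topology test.

.encodeRna <- function(sequence) {
    s <- chartr("acgutT", "ACGUUU", sequence)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    code <- match(v, c("A", "C", "G", "U")) - 1L
    if (anyNA(code))
        stop("invalid character(s) in sequence: ",
             paste(unique(v[is.na(code)]), collapse = ", "),
             " (A/C/G/U/T only)")
    code
}

.hairpinPenaltyVector <- function(params, n) {
    l <- seq_len(max(n, params@minLoop))
    p <- hairpinPenalty(params, l)
    p[!is.finite(p)] <- 1e9
    p
}

#' Fold a sequence to its minimum free energy structure
#'
#' Computes the minimum free energy (MFE) and an optimal dot-bracket
#' structure over all pseudoknot-free secondary structures with pairs
#' AU, UA, GC, CG, GU, UG and hairpin loops of at least
#' \code{params@minLoop} nt. The energy of a structure is defined by
#' \code{\link{structureEnergy}}; the dynamic program returns its exact
#' minimum (the empty structure, energy 0, is always admissible, so the
#' MFE is never positive). Ties are broken deterministically, preferring
#' structures whose outermost pair starts 5'-most. T and U are equivalent.
#'
#' @param sequence single nucleotide string (A/C/G/U/T), length >= 10.
#' @param params an \linkS4class{EnergyParams} object.
#' @return list with elements \code{mfe} (kcal/mol, <= 0) and
#'   \code{structure} (dot-bracket string of the same length).
#' @examples
#' foldMfe("GGGGCCCCAAAAGGGGCCCC")
#' @export
foldMfe <- function(sequence, params = defaultEnergyParams()) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) < 10L)
        stop("sequence must be at least 10 nt (got ", nchar(sequence), ")")
    code <- .encodeRna(sequence)
    hp <- .hairpinPenaltyVector(params, length(code))
    res <- .fold_mfe_cpp(code, params@stack, hp, params@minLoop,
                         params@interiorPenalty)
    list(mfe = res$mfe, structure = res$structure)
}

#' Parse a dot-bracket string into base-pair indices
#'
#' @param structure dot-bracket string using \code{(}, \code{)}, \code{.}.
#' @return two-column integer matrix of 1-based paired positions (i < j).
#' @export
structurePairs <- function(structure) {
    v <- strsplit(structure, "", fixed = TRUE)[[1]]
    if (!all(v %in% c("(", ")", ".")))
        stop("structure may contain only '(', ')' and '.'")
    open <- integer(0)
    pairs <- matrix(integer(0), ncol = 2)
    out <- vector("list", length(v))
    np <- 0L
    for (k in seq_along(v)) {
        if (v[k] == "(") {
            open <- c(open, k)
        } else if (v[k] == ")") {
            if (!length(open)) stop("unbalanced brackets in structure")
            np <- np + 1L
            out[[np]] <- c(open[length(open)], k)
            open <- open[-length(open)]
        }
    }
    if (length(open)) stop("unbalanced brackets in structure")
    if (np == 0L) return(matrix(integer(0), ncol = 2))
    do.call(rbind, out[seq_len(np)])
}

#' Score a secondary structure under the energy model
#'
#' Evaluates the model energy of an explicit structure: for every pair
#' (i, j), if (i+1, j-1) is also a pair, the stacking energy of the two
#' pair types is added; if no position strictly inside (i, j) is paired,
#' the pair closes a hairpin loop and pays the length-dependent penalty;
#' otherwise (bulge, internal loop or multiloop) it pays the flat interior
#' penalty. Unpaired external bases contribute nothing. This function is
#' the single authoritative definition of the energy that
#' \code{\link{foldMfe}} minimizes.
#'
#' @param sequence nucleotide string.
#' @param structure dot-bracket string of the same length.
#' @param params an \linkS4class{EnergyParams} object.
#' @return energy in kcal/mol.
#' @export
structureEnergy <- function(sequence, structure,
                            params = defaultEnergyParams()) {
    code <- .encodeRna(sequence)
    if (nchar(structure) != length(code))
        stop("sequence and structure lengths differ")
    pairs <- structurePairs(structure)
    if (!nrow(pairs)) return(0)
    ptype <- function(i, j) {
        a <- code[i]; b <- code[j]
        key <- paste0(c("A", "C", "G", "U")[a + 1L],
                      c("A", "C", "G", "U")[b + 1L])
        m <- match(key, .PAIR_TYPES)
        if (is.na(m)) stop("illegal base pair ", key, " at (", i, ",", j, ")")
        m
    }
    paired <- logical(length(code))
    paired[pairs] <- TRUE
    pairOf <- integer(length(code))
    pairOf[pairs[, 1]] <- pairs[, 2]
    pairOf[pairs[, 2]] <- pairs[, 1]
    e <- 0
    for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (j - i - 1 < params@minLoop)
            stop("pair (", i, ",", j, ") violates the minimum loop size")
        if (i + 1 <= length(code) && pairOf[i + 1] == j - 1 && j - 1 > i + 1) {
            e <- e + params@stack[ptype(i, j), ptype(i + 1, j - 1)]
        } else if (!any(paired[(i + 1):(j - 1)])) {
            e <- e + hairpinPenalty(params, j - i - 1L)
        } else {
            e <- e + params@interiorPenalty
        }
    }
    e
}

#' Test whether a structure is a single stem-loop hairpin
#'
#' A structure qualifies as a hairpin when it contains exactly one terminal
#' loop (a single stem-loop: bulges and internal loops are allowed, but no
#' multiloops or additional external stems) and at least \code{minPairs}
#' base pairs.
#'
#' @param structure dot-bracket string (must be balanced).
#' @param minPairs minimal number of base pairs (default 15).
#' @return logical.
#' @examples
#' isHairpin(strrep(".", 20))                      # FALSE: no pairs
#' isHairpin(paste0(strrep("(", 16), "...", strrep(")", 16)))
#' @export
isHairpin <- function(structure, minPairs = 15L) {
    pairs <- structurePairs(structure)  # validates balance
    if (nrow(pairs) < minPairs) return(FALSE)
    nloops <- length(gregexpr("\\([.]*\\)", structure)[[1]])
    if (gregexpr("\\([.]*\\)", structure)[[1]][1] == -1L) nloops <- 0L
    nloops == 1L
}
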