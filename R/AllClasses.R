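#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Simulation configuration for synthetic small-RNA experiments
#'
#' Holds every tunable of the synthetic-data generator: the toy genome,
#' the planted hairpin precursors, the library design and the
#' negative-binomial count model. All randomness downstream of a
#' configuration flows from its single \code{seed}; stage-level sub-seeds
#' are derived from it deterministically, so a fixed configuration yields
#' byte-identical output.
#'
#' @slot seed integer; mandatory master seed.
#' @slot chromLengths named integer vector of chromosome lengths (nt).
#' @slot nPrecursors integer; number of hairpin precursors to plant.
#' @slot stemRange integer length-2; stem length range (base pairs).
#' @slot loopRange integer length-2; terminal-loop length range (nt).
#' @slot matureLen integer; mature arm length (nt).
#' @slot armGC numeric; GC fraction of the stem arms.
#' @slot conditions named integer vector: libraries per condition label.
#' @slot tissue character; tissue label recorded in the design table.
#' @slot meanRange numeric length-2; range of true per-locus base means
#'   (reads), sampled log-uniformly.
#' @slot dispersionRange numeric length-2; NB dispersion range (alpha, with
#'   variance \code{m + alpha*m^2}).
#' @slot deFraction numeric; fraction of planted precursor loci that are
#'   differentially expressed.
#' @slot foldChange numeric; fold change applied to DE loci in
#'   \code{deConditions}.
#' @slot deConditions character; condition labels receiving the fold change.
#' @slot sizeFactorRange numeric length-2; range of true library size factors.
#' @slot backgroundPerKb numeric; expected background reads per kb of genome
#'   per library.
#' @slot multimapperRate numeric; fraction of locus reads duplicated to 2-8
#'   alignment positions.
#' @slot jitter integer; maximal 5' end offset of emitted reads (nt).
#' @slot nLowExpressed integer; number of planted precursors whose counts are
#'   capped at \code{lowExpressedCap} in every library (abundance-filter
#'   controls).
#' @slot lowExpressedCap integer; per-library count cap for those loci.
#' @slot nDecoyNcrna integer; number of decoy annotated non-miRNA ncRNA loci.
#' @slot nDecoyExpressed integer; number of unannotated expressed decoy loci
#'   with random (non-hairpin) sequence.
#' @export
setClass("SimulationConfig",
    representation(
        seed = "integer",
        chromLengths = "integer",
        nPrecursors = "integer",
        stemRange = "integer",
        loopRange = "integer",
        matureLen = "integer",
        armGC = "numeric",
        conditions = "integer",
        tissue = "character",
        meanRange = "numeric",
        dispersionRange = "numeric",
        deFraction = "numeric",
        foldChange = "numeric",
        deConditions = "character",
        sizeFactorRange = "numeric",
        backgroundPerKb = "numeric",
        multimapperRate = "numeric",
        jitter = "integer",
        nLowExpressed = "integer",
        lowExpressedCap = "integer",
        nDecoyNcrna = "integer",
        nDecoyExpressed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single non-missing integer")
    if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)))
        msg <- c(msg, "'chromLengths' must be a named integer vector")
    if (any(object@chromLengths <= 0L))
        msg <- c(msg, "all chromosome lengths must be positive")
    if (object@nPrecursors < 0L || object@nDecoyNcrna < 0L ||
        object@nDecoyExpressed < 0L || object@nLowExpressed < 0L)
        msg <- c(msg, "feature counts must be >= 0")
    if (object@nLowExpressed > object@nPrecursors)
        msg <- c(msg, "'nLowExpressed' cannot exceed 'nPrecursors'")
    if (any(object@dispersionRange < 0))
        msg <- c(msg, "dispersions must be >= 0")
    if (any(object@sizeFactorRange <= 0))
        msg <- c(msg, "size factors must be > 0")
    if (object@foldChange <= 0)
        msg <- c(msg, "'foldChange' must be > 0")
    if (object@deFraction < 0 || object@deFraction > 1)
        msg <- c(msg, "'deFraction' must lie in [0,1]")
    if (any(object@conditions < 0L) || is.null(names(object@conditions)))
        msg <- c(msg, "'conditions' must be a named vector of counts >= 0")
    if (object@jitter < 0L)
        msg <- c(msg, "'jitter' must be >= 0")
    if (object@multimapperRate < 0 || object@multimapperRate > 1)
        msg <- c(msg, "'multimapperRate' must lie in [0,1]")
    if (object@backgroundPerKb < 0)
        msg <- c(msg, "'backgroundPerKb' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults mirror the study design the package was built around: one tissue
#' with five condition groups of three libraries each (healthy \code{H},
#' osteochondrosis-affected \code{OC}, and loaded/unloaded explant groups
#' \code{H_L}, \code{H_UL}, \code{OC_L}), 30 planted precursors on a 50-kb
#' toy chromosome, reads of 20-22 nt from one mature arm with +-1 nt 5'
#' jitter, and NB counts with dispersion 0.05-0.3.
#'
#' @param seed integer master seed (mandatory).
#' @param chromLengths,nPrecursors,stemRange,loopRange,matureLen,armGC,
#'   conditions,tissue,meanRange,dispersionRange,deFraction,foldChange,
#'   deConditions,sizeFactorRange,backgroundPerKb,multimapperRate,jitter,
#'   nLowExpressed,lowExpressedCap,nDecoyNcrna,nDecoyExpressed
#'   see the corresponding \linkS4class{SimulationConfig} slots.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nPrecursors = 5L,
#'                         conditions = c(H = 3L, OC = 3L))
#' @export
simulationConfig <- function(seed,
                             chromLengths = c(chr1 = 50000L),
                             nPrecursors = 30L,
                             stemRange = c(26L, 30L),
                             loopRange = c(6L, 8L),
                             matureLen = 21L,
                             armGC = 0.6,
                             conditions = c(H = 3L, OC = 3L, H_L = 3L,
                                            H_UL = 3L, OC_L = 3L),
                             tissue = "cartilage",
                             meanRange = c(50, 5000),
                             dispersionRange = c(0.05, 0.3),
                             deFraction = 0.1,
                             foldChange = 4,
                             deConditions = c("OC", "OC_L"),
                             sizeFactorRange = c(0.5, 2),
                             backgroundPerKb = 2,
                             multimapperRate = 0.05,
                             jitter = 1L,
                             nLowExpressed = 0L,
                             lowExpressedCap = 999L,
                             nDecoyNcrna = 10L,
                             nDecoyExpressed = 20L) {
    if (missing(seed)) stop("'seed' is mandatory")
    if (missing(deConditions))
        deConditions <- intersect(deConditions, names(conditions))
    new("SimulationConfig",
        seed = as.integer(seed),
        chromLengths = stats::setNames(as.integer(chromLengths),
                                       names(chromLengths)),
        nPrecursors = as.integer(nPrecursors),
        stemRange = as.integer(stemRange),
        loopRange = as.integer(loopRange),
        matureLen = as.integer(matureLen),
        armGC = armGC,
        conditions = stats::setNames(as.integer(conditions),
                                     names(conditions)),
        tissue = tissue,
        meanRange = as.numeric(meanRange),
        dispersionRange = as.numeric(dispersionRange),
        deFraction = deFraction,
        foldChange = foldChange,
        deConditions = deConditions,
        sizeFactorRange = as.numeric(sizeFactorRange),
        backgroundPerKb = backgroundPerKb,
        multimapperRate = multimapperRate,
        jitter = as.integer(jitter),
        nLowExpressed = as.integer(nLowExpressed),
        lowExpressedCap = as.integer(lowExpressedCap),
        nDecoyNcrna = as.integer(nDecoyNcrna),
        nDecoyExpressed = as.integer(nDecoyExpressed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  seed:", object@seed, "\n")
    cat("  genome:", length(object@chromLengths), "chromosome(s),",
        sum(object@chromLengths), "nt\n")
    cat("  planted precursors:", object@nPrecursors,
        sprintf("(stem %d-%d bp, loop %d-%d nt)",
                object@stemRange[1], object@stemRange[2],
                object@loopRange[1], object@loopRange[2]), "\n")
    cat("  libraries:", sum(object@conditions), "in",
        length(object@conditions), "condition group(s)\n")
    cat("  decoys:", object@nDecoyNcrna, "ncRNA,",
        object@nDecoyExpressed, "expressed\n")
})

#' Energy parameters for the secondary-structure model
#'
#' The folding engine scores a pseudoknot-free structure as the sum of
#' stacking energies over immediately nested pair neighbours, plus a
#' positive length-dependent penalty for each hairpin loop, plus a flat
#' positive penalty for each pair that closes neither a stack nor a hairpin
#' (bulge / internal loop / multiloop initiation). Stacking energies are
#' indexed by the outer and inner pair type in the order AU, UA, GC, CG,
#' GU, UG. The hairpin penalty for loop length L is
#' \code{hairpinBase + hairpinScale * log(L / minLoop)}.
#'
#' @slot stack 6x6 numeric matrix of stacking energies (kcal/mol, negative).
#' @slot hairpinBase numeric; hairpin penalty at the minimal loop length
#'   (kcal/mol, positive).
#' @slot hairpinScale numeric; logarithmic loop-length extrapolation slope.
#' @slot interiorPenalty numeric; flat penalty for a non-stack, non-hairpin
#'   closing pair (kcal/mol, positive).
#' @slot minLoop integer; minimal hairpin loop size (nt, >= 3).
#' @export
setClass("EnergyParams",
    representation(
        stack = "matrix",
        hairpinBase = "numeric",
        hairpinScale = "numeric",
        interiorPenalty = "numeric",
        minLoop = "integer"
    )
)

setValidity("EnergyParams", function(object) {
    msg <- character()
    if (!identical(dim(object@stack), c(6L, 6L)))
        msg <- c(msg, "'stack' must be a 6x6 matrix")
    if (any(object@stack >= 0))
        msg <- c(msg, "stacking energies must be negative")
    if (object@hairpinBase <= 0)
        msg <- c(msg, "'hairpinBase' must be positive")
    if (object@hairpinScale < 0)
        msg <- c(msg, "'hairpinScale' must be >= 0")
    if (object@interiorPenalty < 0)
        msg <- c(msg, "'interiorPenalty' must be >= 0")
    if (object@minLoop < 3L)
        msg <- c(msg, "'minLoop' must be >= 3")
    if (length(msg)) msg else TRUE
})

.PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.defaultStackMatrix <- function() {
    # pair "strength" classes: GC/CG = 3, AU/UA = 2, GU/UG = 1
    strength <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)
    lut <- matrix(NA_real_, 3, 3)
    lut[3, 3] <- -3.3
    lut[3, 2] <- lut[2, 3] <- -2.2
    lut[3, 1] <- lut[1, 3] <- -1.5
    lut[2, 2] <- -1.1
    lut[2, 1] <- lut[1, 2] <- -0.8
    lut[1, 1] <- -0.5
    m <- outer(strength, strength, function(a, b) lut[cbind(a, b)])
    dimnames(m) <- list(.PAIR_TYPES, .PAIR_TYPES)
    m
}

#' Construct energy parameters
#'
#' @param stack 6x6 matrix of stacking energies, rows = outer pair,
#'   columns = inner pair, order AU, UA, GC, CG, GU, UG.
#' @param hairpinBase,hairpinScale,interiorPenalty,minLoop see
#'   \linkS4class{EnergyParams}.
#' @return An \linkS4class{EnergyParams} object.
#' @examples
#' p <- energyParams()
#' hairpinPenalty(p, 4L)
#' @export
energyParams <- function(stack = .defaultStackMatrix(),
                         hairpinBase = 7.0,
                         hairpinScale = 1.078,
                         interiorPenalty = 5.0,
                         minLoop = 3L) {
    new("EnergyParams", stack = stack, hairpinBase = hairpinBase,
        hairpinScale = hairpinScale, interiorPenalty = interiorPenalty,
        minLoop = as.integer(minLoop))
}

#' @rdname energyParams
#' @export
defaultEnergyParams <- function() energyParams()

#' Hairpin-loop penalty for a given loop length
#'
#' @param params an \linkS4class{EnergyParams} object.
#' @param loopLen integer loop length(s) in nt.
#' @return numeric penalty (kcal/mol); \code{Inf} below the minimal loop size.
#' @export
hairpinPenalty <- function(params, loopLen) {
    ifelse(loopLen < params@minLoop, Inf,
           params@hairpinBase +
               params@hairpinScale * log(loopLen / params@minLoop))
}

setMethod("show", "EnergyParams", function(object) {
    cat("EnergyParams (simplified nearest-neighbor model)\n")
    cat("  stacking energies:",
        sprintf("%.1f to %.1f kcal/mol", min(object@stack),
                max(object@stack)), "\n")
    cat("  hairpin penalty:",
        sprintf("%.2f + %.3f*log(L/%d) kcal/mol", object@hairpinBase,
                object@hairpinScale, object@minLoop), "\n")
    cat("  interior/bulge/multiloop penalty:",
        sprintf("%.2f kcal/mol", object@interiorPenalty), "\n")
    cat("  minimum loop:", object@minLoop, "nt\n")
})

#' A synthetic small-RNA experiment with ground truth
#'
#' Container returned by \code{\link{simulateMirnaExperiment}}: the toy
#' genome, the full set of emitted aligned read placements, the library
#' design, and the truth needed by downstream validation (planted precursor
#' coordinates with mature arms, decoy loci, true per-locus per-library
#' counts, true size factors, DE flags).
#'
#' @slot genome \code{DNAStringSet} of chromosome sequences.
#' @slot reads \code{GRanges} of aligned read placements with metadata
#'   columns \code{read_id}, \code{library_id}, \code{seq},
#'   \code{n_alignments}, \code{locus} (truth locus id or \code{NA} for
#'   background), \code{primary} (logical: best placement of the read).
#' @slot precursors \code{GRanges} of planted precursors with mature-arm
#'   intervals, stem/loop geometry, source arm, DE flag and fold change.
#' @slot decoys \code{GRanges} of decoy loci (\code{feature_class} column:
#'   \code{"ncRNA"} annotated decoys, \code{"decoy_expr"} expressed decoys).
#' @slot trueCounts integer matrix, truth loci x libraries: number of
#'   non-background reads emitted per locus per library.
#' @slot trueMeans numeric matrix of true NB means per locus x library.
#' @slot sizeFactors named numeric vector of true library size factors.
#' @slot design \code{DataFrame} with \code{library_id}, \code{tissue},
#'   \code{condition}.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("MirSimulation",
    representation(
        genome = "DNAStringSet",
        reads = "GRanges",
        precursors = "GRanges",
        decoys = "GRanges",
        trueCounts = "matrix",
        trueMeans = "matrix",
        sizeFactors = "numeric",
        design = "DataFrame",
        config = "SimulationConfig"
    )
)

setValidity("MirSimulation", function(object) {
    msg <- character()
    if (length(object@sizeFactors) && any(object@sizeFactors <= 0))
        msg <- c(msg, "true size factors must be > 0")
    if (nrow(object@trueCounts) &&
        any(object@trueCounts < 0))
        msg <- c(msg, "true counts must be >= 0")
    if (length(object@precursors)) {
        m5s <- object@precursors$mature5p_start
        m5e <- object@precursors$mature5p_end
        m3s <- object@precursors$mature3p_start
        m3e <- object@precursors$mature3p_end
        ps <- GenomicRanges::start(object@precursors) - 1L # 0-based
        pe <- GenomicRanges::end(object@precursors)        # exclusive
        if (any(m5s < ps | m5e > pe | m3s < ps | m3e > pe))
            msg <- c(msg, "mature intervals must lie within precursors")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MirSimulation", function(object) {
    cat("MirSimulation\n")
    cat("  genome:", length(object@genome), "chromosome(s),",
        sum(Biostrings::width(object@genome)), "nt\n")
    cat("  libraries:", nrow(object@design), "\n")
    cat("  planted precursors:", length(object@precursors),
        sprintf("(%d DE)", sum(object@precursors$is_de)), "\n")
    cat("  decoy loci:", length(object@decoys), "\n")
    cat("  read placements:", length(object@reads),
        sprintf("(%d background)", sum(is.na(object@reads$locus))), "\n")
})

#' Accessors for MirSimulation components
#'
#' @param x a \linkS4class{MirSimulation}.
#' @return the corresponding slot: genome (\code{DNAStringSet}), reads
#'   (\code{GRanges}), planted precursors (\code{GRanges}), decoys
#'   (\code{GRanges}), truth count matrix, true size factors, or the design
#'   \code{DataFrame}.
#' @name MirSimulation-accessors
NULL

#' @rdname MirSimulation-accessors
#' @export
simGenome <- function(x) x@genome
#' @rdname MirSimulation-accessors
#' @export
simReads <- function(x) x@reads
#' @rdname MirSimulation-accessors
#' @export
simPrecursors <- function(x) x@precursors
#' @rdname MirSimulation-accessors
#' @export
simDecoys <- function(x) x@decoys
#' @rdname MirSimulation-accessors
#' @export
simTrueCounts <- function(x) x@trueCounts
#' @rdname MirSimulation-accessors
#' @export
simSizeFactors <- function(x) x@sizeFactors
#' @rdname MirSimulation-accessors
#' @export
simDesign <- function(x) x@design

#' Between-class analysis result
#'
#' @slot loadings loci x axes matrix of component loadings.
#' @slot scores samples x axes matrix of per-sample scores.
#' @slot groupScores groups x axes matrix of group-mean scores.
#' @slot eigenvalues numeric; between-group variance per axis.
#' @slot varProp numeric; proportion of between-group variance per axis.
#' @slot groups factor of sample group assignments.
#' @export
setClass("BCAResult",
    representation(
        loadings = "matrix",
        scores = "matrix",
        groupScores = "matrix",
        eigenvalues = "numeric",
        varProp = "numeric",
        groups = "factor"
    )
)

setValidity("BCAResult", function(object) {
    msg <- character()
    if (length(object@eigenvalues) &&
        length(object@eigenvalues) > nlevels(object@groups) - 1L)
        msg <- c(msg, "at most (groups - 1) non-degenerate axes")
    if (length(object@varProp) &&
        abs(sum(object@varProp) - 1) > 1e-8)
        msg <- c(msg, "variance proportions must sum to 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BCAResult", function(object) {
    cat("BCAResult:", nlevels(object@groups), "groups,",
        length(object@eigenvalues), "axes\n")
    cat("  between-group variance proportions:",
        paste(sprintf("%.3f", object@varProp), collapse = ", "), "\n")
})

#' Accessors for BCAResult components
#' @param x a \linkS4class{BCAResult}.
#' @return the corresponding component.
#' @name BCAResult-accessors
NULL

#' @rdname BCAResult-accessors
#' @export
bcaLoadings <- function(x) x@loadings
#' @rdname BCAResult-accessors
#' @export
bcaScores <- function(x) x@scores
#' @rdname BCAResult-accessors
#' @export
bcaGroupScores <- function(x) x@groupScores
#' @rdname BCAResult-accessors
#' @export
bcaEigenvalues <- function(x) x@eigenvalues
#' @rdname BCAResult-accessors
#' @export
bcaVarProp <- function(x) x@varProp
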