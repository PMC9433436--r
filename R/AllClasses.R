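#' @import methods
#' @importFrom stats setNames rnorm rlnorm rmultinom lm coef predict
#'   residuals fitted quantile median var sd qt pt approx
#' @importFrom utils read.csv write.csv read.delim head
#' @importFrom BiocGenerics start end width
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## RNA alphabet of the randomized leader window, in the fixed internal order
## used everywhere (lexicographic enumeration, logo rows, design columns).
.BASES <- c("A", "C", "G", "U")
.LEADER_WIDTH <- 6L
.LEADER_POSITIONS <- -6:-1

## Genomically encoded ptRNA-Met leader hexamer, the calibration reference.
.DEFAULT_REFERENCE <- "AAAAAG"

## 3' tail of the tRNA written 5'->3'; R = A for the Met substrate.
.DEFAULT_TAIL <- "ACCA"

#' Ground truth for a simulated substrate pool
#'
#' Holds the true relative specificity constants (k_rel, i.e. relative
#' kcat/Km) and the initial pool composition for all 4096 leader hexamer
#' variants, from which depletion time courses and read counts are simulated.
#'
#' @slot variant character vector of the 4096 hexamers N(-6)...N(-1), 5'->3'.
#' @slot trueKrel positive numeric, one per variant; the reference variant is
#'   exactly 1 by construction.
#' @slot weights per-variant fraction of the pool at the start of the
#'   reaction; sums to 1.
#' @slot reference the calibration hexamer (default `"AAAAAG"`).
#' @export
setClass("SimulationTruth",
    representation(
        variant = "character",
        trueKrel = "numeric",
        weights = "numeric",
        reference = "character"
    )
)

setValidity("SimulationTruth", function(object) {
    msg <- character()
    n <- length(object@variant)
    if (n != 4096L)
        msg <- c(msg, "pool must contain exactly 4^6 = 4096 variants")
    if (anyDuplicated(object@variant))
        msg <- c(msg, "variants must be unique")
    if (!all(grepl("^[ACGU]{6}$", object@variant)))
        msg <- c(msg, "variants must be hexamers over {A,C,G,U}")
    if (length(object@trueKrel) != n || any(!is.finite(object@trueKrel)) ||
        any(object@trueKrel <= 0))
        msg <- c(msg, "trueKrel must be finite and positive for every variant")
    if (length(object@weights) != n || any(object@weights < 0) ||
        abs(sum(object@weights) - 1) > 1e-12)
        msg <- c(msg, "weights must be nonnegative and sum to 1 (tol 1e-12)")
    if (length(object@reference) != 1L ||
        !(object@reference %in% object@variant))
        msg <- c(msg, "reference must be one of the pool variants")
    if (length(msg)) msg else TRUE
})

#' State of the competitively depleting pool at one sampled timepoint
#'
#' @slot exposure the common kinetic exposure integral c shared by all
#'   competing variants (nonnegative).
#' @slot fractionUnreacted per-variant fraction unreacted,
#'   F_i = exp(-k_i * c).
#' @slot totalReacted total fraction of the pool converted, f in [0, 1).
#' @export
setClass("DepletionState",
    representation(
        exposure = "numeric",
        fractionUnreacted = "numeric",
        totalReacted = "numeric"
    )
)

setValidity("DepletionState", function(object) {
    msg <- character()
    if (length(object@exposure) != 1L || object@exposure < 0)
        msg <- c(msg, "exposure must be a single nonnegative number")
    if (any(object@fractionUnreacted <= 0) ||
        any(object@fractionUnreacted > 1))
        msg <- c(msg, "fractionUnreacted must lie in (0, 1]")
    if (length(object@totalReacted) != 1L || object@totalReacted < 0 ||
        object@totalReacted >= 1)
        msg <- c(msg, "totalReacted must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Read counts of the residual substrate pool
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per leader
#' variant (all 4096 rows always present, zeros kept) and one column per
#' sequenced sample. Column metadata records the replicate id and the total
#' fraction of substrate reacted `f` at which the sample was drawn (`f = 0`
#' for the reaction-start sample; exactly one per replicate).
#'
#' @export
setClass("PoolCounts", contains = "SummarizedExperiment")

setValidity("PoolCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    if (nrow(object) != 4096L)
        msg <- c(msg, "PoolCounts must have 4096 rows (all hexamers)")
    cd <- colData(object)
    if (!all(c("replicate", "f") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'replicate' and 'f'")
    } else {
        f <- cd$f
        if (any(f < 0) || any(f >= 1))
            msg <- c(msg, "f must lie in [0, 1)")
        n0 <- tapply(f == 0, cd$replicate, sum)
        if (any(n0 != 1L))
            msg <- c(msg, "each replicate needs exactly one f = 0 sample")
    }
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- assay(object, "counts")
        if (any(cts < 0))
            msg <- c(msg, "counts must be nonnegative")
        if (ncol(cts) > 0 && any(colSums(cts) <= 0))
            msg <- c(msg, "every sample must have a positive total count")
    }
    if (length(msg)) msg else TRUE
})

#' Relative rate constants estimated by internal competition
#'
#' Per-variant relative kcat/Km (k_rel) calibrated to the reference leader,
#' with standard errors on the log scale, per-timepoint estimates, read
#' support and censoring flags.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `variant`, `krel`,
#'   `se` (SE of ln k_rel), `nTimepoints`, `reads0` (reference-sample read
#'   support) and `flag` (`"ok"`, `"censored_low"` or `"unobserved"`), plus a
#'   matrix column `perTimepoint` of per-sample estimates.
#' @slot reference the calibration hexamer; its k_rel is exactly 1.
#' @export
setClass("RelRateTable",
    representation(table = "DataFrame", reference = "character")
)

setValidity("RelRateTable", function(object) {
    msg <- character()
    need <- c("variant", "krel", "se", "nTimepoints", "flag")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
    else {
        ok <- object@table$flag == "ok"
        if (any(ok & !(object@table$krel > 0), na.rm = TRUE))
            msg <- c(msg, "unflagged k_rel must be positive")
        i <- match(object@reference, object@table$variant)
        if (is.na(i) || abs(object@table$krel[i] - 1) > 1e-12)
            msg <- c(msg, "reference variant must have k_rel = 1 after calibration")
    }
    if (length(msg)) msg else TRUE
})

#' Sequence-specificity model: PWM main effects plus pairwise interactions
#'
#' Linear model for ln(k_rel) with one coefficient per base per leader
#' position (sum-to-zero within each position, so coefficients read as
#' enrichment relative to the position average) and a set of admitted
#' pairwise interaction indicator terms.
#'
#' @slot intercept model intercept on the ln k_rel scale.
#' @slot mainEffects 4 x 6 matrix (rows A, C, G, U; columns positions -6
#'   through -1) of per-position coefficients; columns sum to zero.
#' @slot mainSE same shape, standard errors of the constrained coefficients
#'   (the U row carries the SE implied by the sum-to-zero constraint).
#' @slot interactions data.frame of admitted terms: `pos1`, `pos2` (negative
#'   position labels, pos1 < pos2), `base1`, `base2`, `alpha`, `se`,
#'   `tvalue` (joint refit), `tAdmission` (screening t in the admission
#'   round), `round`.
#' @slot r2,sigma,nobs,df.residual fit diagnostics.
#' @slot history per-round selection log.
#' @export
setClass("SpecificityModel",
    representation(
        intercept = "numeric",
        mainEffects = "matrix",
        mainSE = "matrix",
        interactions = "data.frame",
        r2 = "numeric",
        sigma = "numeric",
        nobs = "integer",
        df.residual = "integer",
        history = "list"
    )
)

setValidity("SpecificityModel", function(object) {
    msg <- character()
    me <- object@mainEffects
    if (!all(dim(me) == c(4L, 6L)))
        msg <- c(msg, "mainEffects must be 4 x 6")
    else if (any(abs(colSums(me)) > 1e-8))
        msg <- c(msg, "mainEffects columns must sum to zero (identifiability)")
    if (nrow(object@interactions) > 0) {
        need <- c("pos1", "pos2", "base1", "base2", "alpha", "tvalue")
        if (!all(need %in% colnames(object@interactions)))
            msg <- c(msg, "interaction table misses required columns")
    }
    if (length(msg)) msg else TRUE
})

#' Nucleotide frequency / information content matrix for a sequence subset
#'
#' @slot freq 4 x 6 column-stochastic matrix of base frequencies (rows A, C,
#'   G, U; columns positions -6...-1).
#' @slot bits per-position information content, 2 + sum p log2 p, in bits
#'   (uniform background).
#' @slot n number of sequences summarized.
#' @export
setClass("LogoMatrix",
    representation(freq = "matrix", bits = "numeric", n = "integer")
)

setValidity("LogoMatrix", function(object) {
    msg <- character()
    if (!all(dim(object@freq) == c(4L, 6L)))
        msg <- c(msg, "freq must be 4 x 6")
    else if (any(abs(colSums(object@freq) - 1) > 1e-12))
        msg <- c(msg, "freq columns must sum to 1")
    if (any(object@bits < -1e-9) || any(object@bits > 2 + 1e-9))
        msg <- c(msg, "information content must lie in [0, 2] bits")
    if (length(msg)) msg else TRUE
})

#' Maximum base-pairing between a 5' leader window and the 3' tail
#'
#' Result of the antiparallel, non-crossing maximum-cardinality pairing
#' dynamic program (Watson-Crick plus G:U wobble; bulges allowed on either
#' strand).
#'
#' @slot leader,tail the two strands, 5'->3'.
#' @slot nPairs maximum number of base pairs.
#' @slot trace data.frame of the optimal pairing: `leaderPos` (1-based in the
#'   window), `tailPos` (1-based 5'->3' in the tail), `type` ("WC" or
#'   "wobble"); mutually exclusive and non-crossing, tie-broken toward pairs
#'   closest to the cleavage site.
#' @export
setClass("DuplexResult",
    representation(
        leader = "character",
        tail = "character",
        nPairs = "integer",
        trace = "data.frame"
    )
)

setValidity("DuplexResult", function(object) {
    msg <- character()
    if (object@nPairs != nrow(object@trace))
        msg <- c(msg, "nPairs must equal the trace length")
    if (nrow(object@trace) > 1) {
        lp <- object@trace$leaderPos
        tp <- object@trace$tailPos
        if (anyDuplicated(lp) || anyDuplicated(tp))
            msg <- c(msg, "trace pairs must be mutually exclusive")
        o <- order(lp)
        ## antiparallel: increasing leader position pairs decreasing tail pos
        if (any(diff(tp[o]) >= 0))
            msg <- c(msg, "trace must be non-crossing (antiparallel monotone)")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted single-substrate assay
#'
#' Container for Michaelis-Menten, equilibrium binding, dissociation and
#' initial-rate fits.
#'
#' @slot assay one of `"michaelis_menten"`, `"binding"`, `"dissociation"`,
#'   `"initial_rate"`.
#' @slot coef named parameter estimates (e.g. `kcat`, `Km`, `kcatKm`; `Kd`,
#'   `Bmax`; `Afast`, `Aslow`, `kfast`, `kslow`).
#' @slot se standard errors matching `coef` (delta method for derived
#'   quantities such as kcat/Km).
#' @slot vcov covariance matrix of the primary fitted parameters.
#' @slot fitted,residuals fitted values and residuals at the data points.
#' @slot data the data used in the fit.
#' @slot info diagnostics (convergence, weighting, model selection, flags).
#' @export
setClass("AssayFit",
    representation(
        assay = "character",
        coef = "numeric",
        se = "numeric",
        vcov = "matrix",
        fitted = "numeric",
        residuals = "numeric",
        data = "data.frame",
        info = "list"
    )
)
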